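#' Spatial data containers
#'
#' Light S3 containers shared by all stages of the workflow:
#'
#' * `transcript_table()` — per-molecule records with global (x, y) µm
#'   coordinates, gene identity and a decoding quality score (`qv`).
#' * `intensity_image()` — a non-negative 2-D array (rows = y, cols = x)
#'   plus the [pixel_frame()] placing it in µm space; holds DAPI stains and
#'   transcript-density pseudoimages.
#' * `label_mask()` — an integer instance image (0 = background, each
#'   positive integer one cell or nucleus) plus its frame.
#' * `cell_polygon()` — an ordered, implicitly closed boundary polygon in µm
#'   with a cell label.
#'
#' @param x,y,gene,qv Equal-length vectors: coordinates in µm (finite),
#'   non-empty gene identifiers, quality scores (>= 0).
#' @param ... Additional equal-length columns carried through unchanged
#'   (e.g. a ground-truth `cell` column from the simulator).
#' @return The respective container object.
#' @name containers
NULL

#' @rdname containers
#' @export
transcript_table <- function(x = numeric(), y = numeric(),
                             gene = character(), qv = numeric(), ...) {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   gene = as.character(gene), qv = as.numeric(qv),
                   ...,
                   stringsAsFactors = FALSE)
  validate_transcripts(df)
  class(df) <- c("transcript_table", "data.frame")
  df
}

validate_transcripts <- function(df) {
  need <- c("x", "y", "gene", "qv")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("transcript table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
      stop("transcript coordinates must be finite")
    if (any(is.na(df$qv) | df$qv < 0))
      stop("transcript qv must be >= 0")
    if (any(is.na(df$gene) | !nzchar(df$gene)))
      stop("transcript gene identifiers must be non-empty")
  }
  invisible(df)
}

as_transcript_table <- function(df) {
  validate_transcripts(df)
  if (!inherits(df, "transcript_table"))
    class(df) <- c("transcript_table", class(df))
  df
}

#' @rdname containers
#' @param values Numeric matrix of non-negative intensities, `frame$height`
#'   rows by `frame$width` columns.
#' @param frame A [pixel_frame()].
#' @export
intensity_image <- function(values, frame) {
  assert_frame(frame)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != frame$height || ncol(values) != frame$width)
    stop(sprintf("image is %d x %d but frame is %d x %d (rows x cols)",
                 nrow(values), ncol(values), frame$height, frame$width))
  if (any(!is.finite(values)) || any(values < 0))
    stop("intensity values must be finite and non-negative")
  structure(list(values = values, frame = frame), class = "intensity_image")
}

#' @rdname containers
#' @param labels Integer matrix of instance labels (>= 0), background 0.
#' @export
label_mask <- function(labels, frame) {
  assert_frame(frame)
  labels <- as.matrix(labels)
  if (any(is.na(labels)) || any(labels < 0) || any(labels != floor(labels)))
    stop("mask labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  if (nrow(labels) != frame$height || ncol(labels) != frame$width)
    stop(sprintf("mask is %d x %d but frame is %d x %d (rows x cols)",
                 nrow(labels), ncol(labels), frame$height, frame$width))
  structure(list(labels = labels, frame = frame), class = "label_mask")
}

#' @rdname containers
#' @param vertices An n x 2 matrix (n >= 3) of (x, y) µm boundary vertices in
#'   order; the polygon is implicitly closed (last vertex connects back to
#'   the first) and must be simple.
#' @param label Cell identifier.
#' @export
cell_polygon <- function(vertices, label) {
  v <- as_xy_matrix(vertices)
  if (nrow(v) < 3L) stop("a cell polygon needs at least 3 vertices")
  if (any(!is.finite(v))) stop("polygon vertices must be finite")
  structure(list(vertices = v, label = label), class = "cell_polygon")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %s, range [%g, %g]\n",
              format(x$frame), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %s, %d instance(s)\n",
              format(x$frame), length(mask_labels(x))))
  invisible(x)
}

#' @export
print.cell_polygon <- function(x, ...) {
  cat(sprintf("<cell_polygon> label %s, %d vertices\n",
              format(x$label), nrow(x$vertices)))
  invisible(x)
}

#' Instance labels present in a mask
#'
#' @param mask A [label_mask()].
#' @return Sorted integer vector of the positive labels present.
#' @export
mask_labels <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  u <- sort(unique(as.integer(mask$labels)))
  u[u > 0L]
}

#' Relabel mask instances to contiguous 1..n
#'
#' Keeps instance identity order (ascending original label) and returns the
#' mapping used.
#'
#' @param mask A [label_mask()].
#' @return A [label_mask()] with attribute `"mapping"`: a named integer
#'   vector, new label -> old label.
#' @export
relabel_mask <- function(mask) {
  old <- mask_labels(mask)
  lab <- mask$labels
  if (length(old)) {
    new <- match(lab, old, nomatch = 0L)
    lab <- matrix(as.integer(new), nrow(lab), ncol(lab))
  }
  out <- label_mask(lab, mask$frame)
  attr(out, "mapping") <- stats::setNames(old, seq_along(old))
  out
}
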