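#' Pixel frame: the discrete grid underlying images and masks
#'
#' A `pixel_frame` places a `height` x `width` pixel grid into global
#' micrometre coordinates.  The frame origin is the top-left corner of pixel
#' (1, 1); x increases with column index, y increases with row index
#' (y-down, the usual imaging convention).  Pixel (r, c) covers the half-open
#' box x in `[origin[1] + (c-1)*s, origin[1] + c*s)` and y likewise, where
#' `s` is `pixel_size` in micrometres per pixel.
#'
#' @param width,height Grid dimensions in pixels (positive integers).
#' @param pixel_size Pixel edge length in micrometres per pixel. The default
#'   0.2125 is the Xenium mosaic resolution.
#' @param origin Length-2 numeric, global (x, y) micrometre offset of the
#'   frame's top-left corner.
#' @return An object of class `pixel_frame`.
#' @examples
#' fr <- pixel_frame(256, 256, pixel_size = 0.5)
#' um_to_px(c(1, 0), fr)
#' @export
pixel_frame <- function(width, height, pixel_size = 0.2125, origin = c(0, 0)) {
  width <- as.integer(width)
  height <- as.integer(height)
  stopifnot(length(width) == 1L, length(height) == 1L)
  if (is.na(width) || width <= 0L || is.na(height) || height <= 0L)
    stop("frame width and height must be positive integers")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive finite number (µm per pixel)")
  if (!is.numeric(origin) || length(origin) != 2L || any(!is.finite(origin)))
    stop("origin must be a finite (x, y) pair in µm")
  structure(
    list(width = width, height = height,
         pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin)),
    class = "pixel_frame")
}

is_pixel_frame <- function(x) inherits(x, "pixel_frame")

assert_frame <- function(frame) {
  if (!is_pixel_frame(frame)) stop("expected a 'pixel_frame' object")
  invisible(frame)
}

#' @export
print.pixel_frame <- function(x, ...) {
  cat(sprintf("<pixel_frame> %d x %d px @ %g µm/px, origin (%g, %g) µm\n",
              x$width, x$height, x$pixel_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
format.pixel_frame <- function(x, ...) {
  sprintf("%dx%d@%g", x$width, x$height, x$pixel_size)
}

frames_equal <- function(a, b, tol = 1e-9) {
  a$width == b$width && a$height == b$height &&
    abs(a$pixel_size - b$pixel_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' Convert micrometre coordinates to pixel indices and back
#'
#' `um_to_px()` maps global micrometre points onto 1-based `(row, col)` pixel
#' indices of a frame using the half-open pixel convention: pixel `(r, c)`
#' covers `x` in `[origin_x + (c-1)*s, origin_x + c*s)` and `y` in
#' `[origin_y + (r-1)*s, origin_y + r*s)`.  `px_to_um()` returns pixel
#' centres.  Indices outside `1..height` / `1..width` are returned as-is;
#' callers decide how to treat out-of-frame points.
#'
#' @param points Numeric vector `c(x, y)` or an n x 2 matrix of (x, y) µm.
#' @param frame A [pixel_frame()].
#' @return `um_to_px()`: an n x 2 integer matrix of `(row, col)` indices;
#'   `px_to_um()`: an n x 2 numeric matrix of (x, y) pixel-centre µm.
#' @export
um_to_px <- function(points, frame) {
  assert_frame(frame)
  p <- as_xy_matrix(points)
  s <- frame$pixel_size
  col <- floor((p[, 1] - frame$origin[1]) / s) + 1
  row <- floor((p[, 2] - frame$origin[2]) / s) + 1
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @rdname um_to_px
#' @param idx Integer vector `c(row, col)` or an n x 2 matrix of indices.
#' @export
px_to_um <- function(idx, frame) {
  assert_frame(frame)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 2, byrow = FALSE,
                                       dimnames = NULL)
  if (length(idx) == 2L && is.null(dim(idx))) idx <- matrix(idx, ncol = 2)
  idx <- matrix(as.numeric(idx), ncol = 2)
  s <- frame$pixel_size
  cbind(x = frame$origin[1] + (idx[, 2] - 0.5) * s,
        y = frame$origin[2] + (idx[, 1] - 0.5) * s)
}

as_xy_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 2L) stop("expected c(x, y) or an n x 2 matrix")
    points <- matrix(points, ncol = 2)
  }
  m <- as.matrix(points)
  if (ncol(m) != 2L) stop("expected an n x 2 matrix of (x, y) coordinates")
  storage.mode(m) <- "double"
  m
}

# µm coordinates of all pixel centres, as (x, y) matrices the same shape
# as the image array (rows = y, cols = x)
pixel_center_grid <- function(frame) {
  s <- frame$pixel_size
  xs <- frame$origin[1] + (seq_len(frame$width) - 0.5) * s
  ys <- frame$origin[2] + (seq_len(frame$height) - 0.5) * s
  list(x = xs, y = ys)
}
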