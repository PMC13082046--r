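#' Crop images, masks and transcript tables to a pixel window
#'
#' A window is an integer vector `c(row, col, nrow, ncol)`: the 1-based top
#' left pixel of the window within the frame plus its size in pixels.  The
#' cropped object gets a frame whose origin is shifted to the window's top
#' left corner, so global µm coordinates are preserved.  For transcript
#' tables a `frame` must be supplied and molecules whose coordinates fall
#' outside the window's half-open µm box are dropped.
#'
#' @param x An [intensity_image()], [label_mask()] or [transcript_table()].
#' @param window Integer `c(row, col, nrow, ncol)` in pixels.
#' @param frame Required for transcript tables: the [pixel_frame()] the
#'   window refers to.
#' @param ... Unused.
#' @return Object of the same class restricted to the window.
#' @export
crop <- function(x, window, ...) UseMethod("crop")

check_window <- function(window, frame) {
  window <- as.integer(window)
  if (length(window) != 4L || any(is.na(window)))
    stop("window must be c(row, col, nrow, ncol)")
  if (window[3] <= 0L || window[4] <= 0L)
    stop("empty crop window")
  if (window[1] < 1L || window[2] < 1L ||
      window[1] + window[3] - 1L > frame$height ||
      window[2] + window[4] - 1L > frame$width)
    stop("crop window extends outside the frame")
  window
}

window_frame <- function(window, frame) {
  s <- frame$pixel_size
  pixel_frame(window[4], window[3], s,
              origin = frame$origin + c((window[2] - 1L) * s,
                                        (window[1] - 1L) * s))
}

#' @rdname crop
#' @export
crop.intensity_image <- function(x, window, ...) {
  w <- check_window(window, x$frame)
  rows <- seq.int(w[1], length.out = w[3])
  cols <- seq.int(w[2], length.out = w[4])
  intensity_image(x$values[rows, cols, drop = FALSE], window_frame(w, x$frame))
}

#' @rdname crop
#' @export
crop.label_mask <- function(x, window, ...) {
  w <- check_window(window, x$frame)
  rows <- seq.int(w[1], length.out = w[3])
  cols <- seq.int(w[2], length.out = w[4])
  label_mask(x$labels[rows, cols, drop = FALSE], window_frame(w, x$frame))
}

#' @rdname crop
#' @export
crop.transcript_table <- function(x, window, frame, ...) {
  assert_frame(frame)
  w <- check_window(window, frame)
  s <- frame$pixel_size
  x0 <- frame$origin[1] + (w[2] - 1L) * s
  y0 <- frame$origin[2] + (w[1] - 1L) * s
  x1 <- x0 + w[4] * s
  y1 <- y0 + w[3] * s
  keep <- x$x >= x0 & x$x < x1 & x$y >= y0 & x$y < y1
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_transcript_table(out)
}
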