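#' Parameters of the transcript-density pseudoimage
#'
#' The pseudoimage is built by placing an isotropic 2-D Gaussian kernel at
#' each retained transcript location and summing contributions on the pixel
#' grid:
#' \deqn{f(u) = \sum_i \exp(-\|u - x_i\|^2 / (2\sigma^2))}
#' `sigma` is interpreted in pixels by default (set `sigma_units = "um"` to
#' give it in micrometres; it is converted via the frame's pixel size).
#' Kernels are truncated at `kernel_truncation * sigma` (radial cutoff);
#' with the default 4 the per-transcript error is below `exp(-8)`.
#'
#' @param sigma Gaussian spread; default 2.5.
#' @param kernel_truncation Cutoff radius in multiples of sigma (>= 3).
#' @param qv_min Quality threshold; transcripts with `qv < qv_min` are
#'   ignored. Default 20.
#' @param sigma_units `"px"` or `"um"`.
#' @return A `density_params` object.
#' @export
density_params <- function(sigma = 2.5, kernel_truncation = 4, qv_min = 20,
                           sigma_units = c("px", "um")) {
  sigma_units <- match.arg(sigma_units)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            is.numeric(kernel_truncation), kernel_truncation >= 3,
            is.numeric(qv_min), qv_min >= 0)
  structure(list(sigma = sigma, kernel_truncation = kernel_truncation,
                 qv_min = qv_min, sigma_units = sigma_units),
            class = "density_params")
}

#' Normalize a DAPI image by its 99th percentile
#'
#' Caps pixel values at the image-wide 99th percentile (R's default
#' quantile interpolation, type 7) and divides by it, yielding values in
#' `[0, 1]`.  An all-zero image (99th percentile 0) maps to all zeros.
#'
#' @param raw An [intensity_image()] with non-negative values.
#' @param probs Percentile used for capping (default 0.99).
#' @return An [intensity_image()] in `[0, 1]`.
#' @export
normalize_dapi <- function(raw, probs = 0.99) {
  stopifnot(inherits(raw, "intensity_image"))
  q <- stats::quantile(raw$values, probs, names = FALSE)
  v <- if (q <= 0) {
    matrix(0, nrow(raw$values), ncol(raw$values))
  } else {
    pmin(raw$values, q) / q
  }
  intensity_image(v, raw$frame)
}

#' Gaussian transcript-density map
#'
#' Evaluates the kernel-sum density at every pixel centre of `frame` for
#' all transcripts with `qv >= params$qv_min`.  The result is unscaled: an
#' isolated transcript sitting exactly on a pixel centre contributes 1
#' there.  Use [scale_unit()] (or [build_stack()]) for the `[0, 1]` model
#' input.
#'
#' @param transcripts A [transcript_table()].
#' @param frame A [pixel_frame()].
#' @param params A [density_params()].
#' @return An [intensity_image()] (unscaled kernel sums).
#' @export
density_map <- function(transcripts, frame, params = density_params()) {
  assert_frame(frame)
  validate_transcripts(transcripts)
  stopifnot(inherits(params, "density_params"))
  s <- frame$pixel_size
  sigma_px <- if (params$sigma_units == "um") params$sigma / s else params$sigma
  rad <- params$kernel_truncation * sigma_px
  keep <- transcripts$qv >= params$qv_min
  tx <- transcripts[keep, , drop = FALSE]
  vals <- matrix(0, frame$height, frame$width)
  if (nrow(tx) == 0L) return(intensity_image(vals, frame))
  # transcript positions in continuous pixel coordinates (pixel centre of
  # pixel (r, c) is at (r - 0.5, c - 0.5))
  pc <- (tx$x - frame$origin[1]) / s
  pr <- (tx$y - frame$origin[2]) / s
  inv2s2 <- 1 / (2 * sigma_px ^ 2)
  rad2 <- rad ^ 2
  for (i in seq_len(nrow(tx))) {
    rlo <- max(1L, ceiling(pr[i] - rad + 0.5))
    rhi <- min(frame$height, floor(pr[i] + rad + 0.5))
    clo <- max(1L, ceiling(pc[i] - rad + 0.5))
    chi <- min(frame$width, floor(pc[i] + rad + 0.5))
    if (rlo > rhi || clo > chi) next
    dr2 <- ((rlo:rhi) - 0.5 - pr[i]) ^ 2
    dc2 <- ((clo:chi) - 0.5 - pc[i]) ^ 2
    d2 <- outer(dr2, dc2, "+")
    k <- exp(-d2 * inv2s2)
    k[d2 > rad2] <- 0
    vals[rlo:rhi, clo:chi] <- vals[rlo:rhi, clo:chi] + k
  }
  intensity_image(vals, frame)
}

#' Linearly rescale an image to the unit interval
#'
#' `(v - min) / (max - min)`; a constant image maps to all zeros so empty
#' tiles stay empty.  Idempotent on images already spanning `[0, 1]`.
#'
#' @param img An [intensity_image()].
#' @return An [intensity_image()] in `[0, 1]`.
#' @export
scale_unit <- function(img) {
  stopifnot(inherits(img, "intensity_image"))
  lo <- min(img$values); hi <- max(img$values)
  v <- if (hi - lo <= 0) {
    matrix(0, nrow(img$values), ncol(img$values))
  } else {
    (img$values - lo) / (hi - lo)
  }
  intensity_image(v, img$frame)
}

#' Two-channel model input: normalized DAPI plus scaled density
#'
#' @param dapi An [intensity_image()] in `[0, 1]`.
#' @param density An [intensity_image()] in `[0, 1]`, same frame.
#' @return A `channel_stack` with fields `dapi`, `density`, `frame`.
#' @export
channel_stack <- function(dapi, density) {
  stopifnot(inherits(dapi, "intensity_image"),
            inherits(density, "intensity_image"))
  if (!frames_equal(dapi$frame, density$frame))
    stop("channel frames differ")
  if (max(dapi$values) > 1 + 1e-12 || max(density$values) > 1 + 1e-12)
    stop("channel values must lie in [0, 1]; scale them first")
  structure(list(dapi = dapi, density = density, frame = dapi$frame),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %s (dapi + transcript density)\n",
              format(x$frame)))
  invisible(x)
}

#' @rdname channel_stack
#' @param dapi_raw Raw (unnormalized) DAPI [intensity_image()] on `frame`.
#' @param transcripts A [transcript_table()].
#' @param frame Target [pixel_frame()].
#' @param params A [density_params()].
#' @export
build_stack <- function(dapi_raw, transcripts, frame,
                        params = density_params()) {
  assert_frame(frame)
  stopifnot(inherits(dapi_raw, "intensity_image"))
  if (!frames_equal(dapi_raw$frame, frame))
    stop("DAPI frame does not match the target frame")
  channel_stack(normalize_dapi(dapi_raw),
                scale_unit(density_map(transcripts, frame, params)))
}
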