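#' Boundary-constrained nuclear expansion
#'
#' The classical whole-cell baseline: every background pixel is annexed by
#' the nearest nucleus (Euclidean distance between pixel centres) provided
#' that distance is at most `distance_um`; expansion fronts of neighbouring
#' nuclei meet midway (a nearest-nucleus constraint, so no instance ever
#' grows across another's territory).  Nucleus pixels keep their labels.
#' Pixels exactly equidistant from two nuclei go to the smaller label.
#'
#' @param nuclei A [label_mask()] of nuclear instances.
#' @param distance_um Expansion distance in micrometres (default 5, the
#'   Xenium Ranger convention).
#' @return A [label_mask()] of expanded whole-cell instances, each
#'   containing its nucleus.
#' @export
expand_nuclei <- function(nuclei, distance_um = 5) {
  stopifnot(inherits(nuclei, "label_mask"),
            is.numeric(distance_um), distance_um >= 0)
  s <- nuclei$frame$pixel_size
  if (!is.finite(s) || s <= 0)
    stop("mask frame lacks a valid pixel_size; the distance is in µm")
  if (distance_um == 0) return(nuclei)
  rad_px <- distance_um / s
  H <- nuclei$frame$height; W <- nuclei$frame$width
  best_d2 <- matrix(Inf, H, W)
  best_lab <- matrix(0L, H, W)
  labs <- mask_labels(nuclei)
  m <- ceiling(rad_px)
  for (lab in labs) {
    px <- which(nuclei$labels == lab, arr.ind = TRUE)
    rlo <- max(1L, min(px[, 1]) - m); rhi <- min(H, max(px[, 1]) + m)
    clo <- max(1L, min(px[, 2]) - m); chi <- min(W, max(px[, 2]) + m)
    rows <- rlo:rhi; cols <- clo:chi
    # squared distance from every box pixel to this nucleus's pixel set
    d2 <- matrix(Inf, length(rows), length(cols))
    dr2 <- outer(rows, px[, 1], function(a, b) (a - b) ^ 2)
    dc2 <- outer(cols, px[, 2], function(a, b) (a - b) ^ 2)
    for (k in seq_len(nrow(px)))
      d2 <- pmin(d2, outer(dr2[, k], dc2[, k], "+"))
    sub_d <- best_d2[rows, cols, drop = FALSE]
    sub_l <- best_lab[rows, cols, drop = FALSE]
    # strict improvement wins; ties keep the earlier (smaller) label
    upd <- d2 < sub_d
    sub_d[upd] <- d2[upd]
    sub_l[upd] <- lab
    best_d2[rows, cols] <- sub_d
    best_lab[rows, cols] <- sub_l
  }
  out <- best_lab
  out[best_d2 > rad_px ^ 2 + 1e-9] <- 0L
  # nucleus pixels always keep their own labels (distance 0 guarantees it,
  # but make it explicit for overlapping inputs)
  nz <- nuclei$labels > 0L
  out[nz] <- nuclei$labels[nz]
  label_mask(out, nuclei$frame)
}

#' Classical fallback segmenter
#'
#' A deterministic, self-contained whole-cell segmenter used to exercise
#' the evaluation stack end-to-end without a trained model: foreground is
#' taken where either channel exceeds its Otsu threshold, seeds are the
#' supplied nuclei (or local maxima of the smoothed DAPI channel when no
#' nuclei are given), and instances are grown from the seeds over the
#' foreground by seeded propagation on the combined intensity.  It is
#' intentionally simple and makes no claim to match a trained model's
#' accuracy.
#'
#' @param stack A [channel_stack()].
#' @param nuclei Optional [label_mask()] of seed nuclei.
#' @return A [label_mask()]; empty (all zero, with a warning) when no seeds
#'   are found.
#' @export
segment_fallback <- function(stack, nuclei = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  dapi <- stack$dapi$values
  dens <- stack$density$values
  fg <- matrix(FALSE, nrow(dapi), ncol(dapi))
  if (max(dens) > min(dens))
    fg <- fg | dens >= otsu_threshold(dens)
  if (max(dapi) > min(dapi))
    fg <- fg | dapi >= otsu_threshold(dapi)
  if (!is.null(nuclei)) {
    stopifnot(inherits(nuclei, "label_mask"))
    if (!frames_equal(nuclei$frame, stack$frame))
      stop("nuclei mask frame does not match the stack frame")
    seeds <- nuclei$labels
    fg <- fg | seeds > 0L
  } else {
    seeds <- dapi_local_maxima(dapi)
  }
  if (!any(seeds > 0L)) {
    warning("no seeds found; returning an empty mask")
    out <- label_mask(matrix(0L, nrow(dapi), ncol(dapi)), stack$frame)
    attr(out, "empty") <- TRUE
    return(out)
  }
  combined <- (dapi + dens) / 2
  lab <- EBImage::propagate(EBImage::Image(t(combined)),
                            EBImage::Image(t(seeds)),
                            mask = t(fg), lambda = 1e-4)
  out <- keep_largest_component(t(EBImage::imageData(lab)))
  label_mask(out, stack$frame)
}

# Otsu threshold on a [0,1]-ish matrix via EBImage
otsu_threshold <- function(v) {
  rng <- range(v)
  EBImage::otsu(EBImage::Image(t((v - rng[1]) / (rng[2] - rng[1])))) *
    (rng[2] - rng[1]) + rng[1]
}

# seed candidates: connected components of smoothed-DAPI local maxima
dapi_local_maxima <- function(dapi, smooth_sigma = 2, min_rel = 0.2) {
  sm <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(dapi)),
                                            sigma = smooth_sigma)))
  H <- nrow(sm); W <- ncol(sm)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- sm
  ismax <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & sm >= pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  ismax <- ismax & sm > min_rel * max(sm)
  lab <- EBImage::bwlabel(EBImage::Image(t(ismax)))
  matrix(as.integer(t(EBImage::imageData(lab))), H, W)
}

#' Segmentation backends
#'
#' `segmentation_backend()` wraps any function mapping a [channel_stack()]
#' to a [label_mask()] (for example an adapter around an external trained
#' model's command-line or file interface).  `segment_external()` invokes
#' the backend, validates the result against the input frame and relabels
#' instances to contiguous positive integers.
#'
#' @param name Backend identifier.
#' @param fun Function `(channel_stack) -> label_mask`.
#' @param capabilities Character vector, e.g. `"two-channel"`.
#' @return `segmentation_backend()`: a backend object; `segment_external()`:
#'   a [label_mask()].
#' @export
segmentation_backend <- function(name, fun,
                                 capabilities = "two-channel") {
  stopifnot(is.character(name), is.function(fun))
  structure(list(name = name, fun = fun, capabilities = capabilities),
            class = "segmentation_backend")
}

#' @rdname segmentation_backend
#' @param stack A [channel_stack()].
#' @param backend A `segmentation_backend`.
#' @export
segment_external <- function(stack, backend) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!inherits(backend, "segmentation_backend"))
    stop("backend unavailable: supply a segmentation_backend object ",
         "wrapping the trained model (see ?segmentation_backend)")
  out <- backend$fun(stack)
  if (!inherits(out, "label_mask"))
    stop("backend '", backend$name, "' did not return a label_mask")
  if (!frames_equal(out$frame, stack$frame))
    stop("backend '", backend$name,
         "' returned a mask on a different frame than its input")
  relabel_mask(out)
}
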