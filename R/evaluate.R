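#' Pixel-level IoU matrix between two instance masks
#'
#' Row `i` / column `j` holds `|G_i ∩ P_j| / |G_i ∪ P_j|` in pixels, where
#' `G_i` are ground-truth instances and `P_j` predicted instances;
#' background (label 0) is excluded from both sides.
#'
#' @param gt,pred [label_mask()]s on the same frame.
#' @return An `iou_matrix` object: list with `gt_labels`, `pred_labels` and
#'   the `values` matrix.
#' @export
iou_matrix <- function(gt, pred) {
  stopifnot(inherits(gt, "label_mask"), inherits(pred, "label_mask"))
  if (!frames_equal(gt$frame, pred$frame))
    stop("ground-truth and predicted masks are on different frames")
  gl <- mask_labels(gt)
  pl <- mask_labels(pred)
  g <- as.integer(gt$labels)
  p <- as.integer(pred$labels)
  sel <- g > 0L & p > 0L
  inter <- matrix(0, length(gl), length(pl))
  if (any(sel)) {
    tab <- table(factor(g[sel], levels = gl), factor(p[sel], levels = pl))
    inter <- matrix(as.numeric(tab), length(gl), length(pl))
  }
  gs <- tabulate(match(g, gl), nbins = length(gl))
  ps <- tabulate(match(p, pl), nbins = length(pl))
  uni <- outer(gs, ps, "+") - inter
  vals <- inter / uni
  vals[!is.finite(vals)] <- 0
  structure(list(gt_labels = gl, pred_labels = pl, values = vals),
            class = "iou_matrix")
}

#' Per-predicted-cell image IoU and its tile mean
#'
#' Each predicted cell scores the maximum IoU it reaches against any
#' ground-truth cell (0 when there are none); the tile score is the
#' unweighted mean over predicted cells.  A tile without predicted cells
#' has an undefined mean: `tile_mean` is `NA` and `defined` is `FALSE`, and
#' such tiles are excluded when averaging across tiles.
#'
#' @param m An [iou_matrix()].
#' @return List with `per_pred` (named numeric, one entry per predicted
#'   cell), `tile_mean` and `defined`.
#' @export
image_iou <- function(m) {
  stopifnot(inherits(m, "iou_matrix"))
  np <- length(m$pred_labels)
  if (np == 0L)
    return(list(per_pred = stats::setNames(numeric(0), character(0)),
                tile_mean = NA_real_, defined = FALSE))
  per <- if (length(m$gt_labels) == 0L) rep(0, np) else
    apply(m$values, 2, max)
  list(per_pred = stats::setNames(as.numeric(per), m$pred_labels),
       tile_mean = mean(per), defined = TRUE)
}

#' Assign transcripts to cells by spatial containment
#'
#' Each molecule is assigned the instance label of the pixel containing its
#' coordinate (half-open pixel convention); molecules on background or
#' outside the frame are unassigned (0).
#'
#' @param mask A [label_mask()].
#' @param transcripts A [transcript_table()] (apply
#'   [filter_transcripts()] first to reproduce the quality-controlled
#'   assignment).
#' @return Integer vector, one entry per transcript row: the assigned
#'   label, 0 = unassigned.
#' @export
assign_transcripts <- function(mask, transcripts) {
  stopifnot(inherits(mask, "label_mask"))
  validate_transcripts(transcripts)
  n <- nrow(transcripts)
  if (n == 0L) return(integer(0))
  idx <- um_to_px(cbind(transcripts$x, transcripts$y), mask$frame)
  ok <- idx[, 1] >= 1L & idx[, 1] <= mask$frame$height &
    idx[, 2] >= 1L & idx[, 2] <= mask$frame$width
  out <- integer(n)
  out[ok] <- mask$labels[idx[ok, , drop = FALSE]]
  out
}

#' Transcript-level (gene) IoU between two assignments
#'
#' For ground-truth cell `i` with transcript index set `K_i` and predicted
#' cell `j` with set `L_j`, `GeneIoU(i, j) = |K_i ∩ L_j| / |K_i ∪ L_j|`.
#' Each predicted cell scores its maximum over ground-truth cells; the tile
#' mean averages predicted cells.  Predicted cells with zero assigned
#' transcripts are excluded from the mean (the ratio is undefined for
#' empty sets) and reported in `empty_pred`.
#'
#' @param gt_assign,pred_assign Integer assignment vectors from
#'   [assign_transcripts()] over the same transcript index set.
#' @param pred_labels Optional full set of predicted mask labels; labels
#'   absent from `pred_assign` are then reported in `empty_pred`.
#' @return List with `per_pred`, `tile_mean`, `defined`, `empty_pred`.
#' @export
gene_iou <- function(gt_assign, pred_assign, pred_labels = NULL) {
  if (length(gt_assign) != length(pred_assign))
    stop("assignments cover different transcript index sets")
  gl <- sort(unique(gt_assign[gt_assign > 0L]))
  pl <- sort(unique(pred_assign[pred_assign > 0L]))
  empty <- if (is.null(pred_labels)) integer(0) else
    sort(setdiff(as.integer(pred_labels), pl))
  if (length(pl) == 0L)
    return(list(per_pred = stats::setNames(numeric(0), character(0)),
                tile_mean = NA_real_, defined = FALSE,
                empty_pred = empty))
  sel <- gt_assign > 0L & pred_assign > 0L
  inter <- matrix(0, length(gl), length(pl))
  if (any(sel)) {
    tab <- table(factor(gt_assign[sel], levels = gl),
                 factor(pred_assign[sel], levels = pl))
    inter <- matrix(as.numeric(tab), length(gl), length(pl))
  }
  gs <- tabulate(match(gt_assign, gl), nbins = length(gl))
  ps <- tabulate(match(pred_assign, pl), nbins = length(pl))
  uni <- outer(gs, ps, "+") - inter
  vals <- inter / uni
  vals[!is.finite(vals)] <- 0
  per <- if (length(gl) == 0L) rep(0, length(pl)) else apply(vals, 2, max)
  names(per) <- pl
  list(per_pred = per, tile_mean = mean(per), defined = TRUE,
       empty_pred = empty)
}

#' One-to-one mutual best-match cell alignment
#'
#' Pairs ground-truth cell `g` with predicted cell `p` iff their IoU is at
#' least `threshold`, `p` is `g`'s best-scoring prediction, and `g` is
#' `p`'s best-scoring ground-truth cell.  Exact argmax ties are broken
#' toward the smaller label and flagged.
#'
#' @param m An [iou_matrix()].
#' @param threshold Minimum IoU for a valid pair (default 0.3).
#' @return An `alignment_map`: data frame with columns `gt`, `pred`, `iou`;
#'   attribute `ties` counts tie-broken argmaxes.
#' @export
align_cells <- function(m, threshold = 0.3) {
  stopifnot(inherits(m, "iou_matrix"))
  v <- m$values
  ties <- 0L
  pairs <- list()
  if (length(m$gt_labels) && length(m$pred_labels)) {
    # first index = smaller label wins ties (labels are sorted ascending)
    best_for_gt <- apply(v, 1, which.max)
    best_for_pred <- apply(v, 2, which.max)
    ties <- sum(apply(v, 1, function(r) sum(r == max(r)) > 1L & max(r) > 0)) +
      sum(apply(v, 2, function(cl) sum(cl == max(cl)) > 1L & max(cl) > 0))
    for (gi in seq_along(m$gt_labels)) {
      pj <- best_for_gt[gi]
      if (v[gi, pj] >= threshold && best_for_pred[pj] == gi)
        pairs[[length(pairs) + 1L]] <-
          data.frame(gt = m$gt_labels[gi], pred = m$pred_labels[pj],
                     iou = v[gi, pj])
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gt = integer(), pred = integer(), iou = numeric())
  stopifnot(!anyDuplicated(out$gt), !anyDuplicated(out$pred))
  attr(out, "ties") <- as.integer(ties)
  class(out) <- c("alignment_map", "data.frame")
  out
}
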