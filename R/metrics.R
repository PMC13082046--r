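#' Clustering agreement metrics
#'
#' Computes the adjusted Rand index (ARI), adjusted mutual information
#' (AMI, arithmetic normalization), homogeneity and completeness between
#' two labelings from their contingency table.  AMI's expected mutual
#' information uses the exact hypergeometric model.  Conventions for the
#' degenerate single-cluster cases follow the usual library behaviour:
#' when a labeling has zero conditional entropy the corresponding
#' homogeneity/completeness is 1; two labelings that are both single
#' clusters agree perfectly.
#'
#' @param a,b Equal-length label vectors (any atomic type).
#' @return A `cluster_agreement`: list with `ari`, `ami`, `homogeneity`,
#'   `completeness`.
#' @export
agreement <- function(a, b) {
  if (length(a) != length(b))
    stop("labelings have different lengths: ", length(a), " vs ", length(b))
  n <- length(a)
  if (n == 0L) stop("empty labelings")
  tab <- table(a, b)
  ai <- rowSums(tab); bj <- colSums(tab)

  # --- ARI ---
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  ea <- sum_comb(ai); eb <- sum_comb(bj)
  tot <- choose(n, 2)
  expected <- ea * eb / tot
  max_idx <- (ea + eb) / 2
  ari <- if (max_idx == expected) 1 else
    (idx - expected) / (max_idx - expected)

  # --- entropies and mutual information (natural log) ---
  pa <- ai / n; pb <- bj / n
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  pij <- tab / n
  mi <- sum(ifelse(pij > 0,
                   pij * log(pij / outer(pa, pb)), 0))

  # --- expected MI under the hypergeometric model ---
  emi <- expected_mutual_information(ai, bj, n)
  denom <- (ha + hb) / 2 - emi
  ami <- if (abs(denom) < 1e-15) 1 else (mi - emi) / denom

  # --- homogeneity / completeness (a = classes, b = clusters) ---
  # H(a | b) and H(b | a)
  h_a_given_b <- ha_cond(tab, bj, n)
  h_b_given_a <- ha_cond(t(tab), ai, n)
  homogeneity <- if (ha == 0) 1 else 1 - h_a_given_b / ha
  completeness <- if (hb == 0) 1 else 1 - h_b_given_a / hb

  structure(list(ari = unname(ari), ami = unname(ami),
                 homogeneity = unname(homogeneity),
                 completeness = unname(completeness)),
            class = "cluster_agreement")
}

# conditional entropy H(rows | cols) of a contingency table
ha_cond <- function(tab, colsums, n) {
  h <- 0
  for (j in seq_along(colsums)) {
    nj <- colsums[j]
    if (nj == 0) next
    p <- tab[, j][tab[, j] > 0]
    h <- h - sum(p / n * log(p / nj))
  }
  h
}

# exact E[MI] for the permutation (hypergeometric) null
expected_mutual_information <- function(ai, bj, n) {
  emi <- 0
  lfac <- lfactorial
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      a <- ai[i]; b <- bj[j]
      lo <- max(1, a + b - n)
      hi <- min(a, b)
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lfac(a) + lfac(b) + lfac(n - a) + lfac(n - b) -
          lfac(n) - lfac(nij) - lfac(a - nij) - lfac(b - nij) -
          lfac(n - a - b + nij)
        emi <- emi + exp(lp) * (nij / n) * log(n * nij / (a * b))
      }
    }
  }
  emi
}

#' @export
print.cluster_agreement <- function(x, ...) {
  cat(sprintf(
    "<cluster_agreement> ARI %.4f  AMI %.4f  homogeneity %.4f  completeness %.4f\n",
    x$ari, x$ami, x$homogeneity, x$completeness))
  invisible(x)
}

#' One-vs-rest ROC AUC from scores
#'
#' Mann–Whitney formulation with midrank tie handling, equivalent to the
#' trapezoidal area under the ROC curve with tied scores averaged.
#'
#' @param positive Logical vector: is the observation a positive?
#' @param score Numeric classifier score for the positive class.
#' @return AUC in `[0, 1]`; `NA` if either class is empty.
#' @export
roc_auc <- function(positive, score) {
  stopifnot(length(positive) == length(score))
  pos <- as.logical(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass classification report
#'
#' Pure metric computation from held-out predictions: accuracy, one-vs-rest
#' precision/recall/F1 per class with their macro mean, and macro ROC-AUC
#' from predicted class probabilities.  Classes absent from the truth
#' vector have undefined metrics and are excluded from the macro means
#' (reported in `excluded`).  A class-k F1 with zero TP, FP and FN is
#' taken as 0.
#'
#' @param truth Factor (or coercible) of true classes.
#' @param predicted Factor of predicted classes over the same levels.
#' @param prob Optional numeric matrix of class probabilities, columns
#'   named by class; required for `macro_auc`.
#' @return A `classification_report`: accuracy, macro_f1, macro_auc,
#'   per_class data frame (tp/fp/fn/precision/recall/f1/auc), K, excluded.
#' @export
classification_report <- function(truth, predicted, prob = NULL) {
  truth <- as.factor(truth)
  lev <- levels(truth)
  predicted <- factor(predicted, levels = lev)
  if (length(truth) != length(predicted))
    stop("truth and predicted have different lengths")
  n <- length(truth)
  acc <- sum(as.character(truth) == as.character(predicted), na.rm = TRUE) / n
  per <- lapply(lev, function(k) {
    tp <- sum(truth == k & predicted == k)
    fp <- sum(truth != k & predicted == k)
    fn <- sum(truth == k & predicted != k)
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
      if (tp + fp + fn == 0) NA_real_ else 0
    } else 2 * prec * rec / (prec + rec)
    auc <- if (is.null(prob)) NA_real_ else {
      if (!k %in% colnames(prob))
        stop("probability matrix lacks a column for class ", k)
      roc_auc(truth == k, prob[, k])
    }
    data.frame(class = k, tp = tp, fp = fp, fn = fn,
               precision = prec, recall = rec, f1 = f1, auc = auc)
  })
  per <- do.call(rbind, per)
  present <- table(truth)[lev] > 0
  excluded <- lev[!present]
  macro_f1 <- mean(per$f1[present])
  macro_auc <- if (is.null(prob)) NA_real_ else mean(per$auc[present])
  structure(list(accuracy = acc, macro_f1 = macro_f1,
                 macro_auc = macro_auc, per_class = per,
                 K = sum(present), excluded = excluded),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> K = %d: accuracy %.4f, macro-F1 %.4f, macro-AUC %s\n",
    x$K, x$accuracy, x$macro_f1,
    if (is.na(x$macro_auc)) "NA" else sprintf("%.4f", x$macro_auc)))
  invisible(x)
}
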