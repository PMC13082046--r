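# planted multinomial counts with well-separated per-type profiles
planted_counts <- function(K = 10, n_per = 100, G = 40, seed = 1,
                           depth = 150) {
  set.seed(seed)
  prof <- matrix(rgamma(K * G, 0.3), K, G)
  prof <- prof / rowSums(prof)
  truth <- rep(seq_len(K), each = n_per)
  counts <- t(vapply(truth, function(k)
    rmultinom(1, rpois(1, depth) + 30, prof[k, ])[, 1], integer(G)))
  colnames(counts) <- paste0("g", seq_len(G))
  rownames(counts) <- seq_len(nrow(counts))
  list(counts = counts, truth = truth)
}

test_that("count_matrix counts assigned transcripts per cell and gene", {
  tt <- transcript_table(x = rep(1, 6), y = rep(1, 6),
                         gene = c("X", "X", "X", "Y", "X", "Y"),
                         qv = rep(30, 6))
  assign <- c(1L, 1L, 1L, 1L, 0L, 2L)
  cm <- count_matrix(assign, tt, cells = c(1L, 2L))
  expect_equal(cm["1", "X"], 3L)
  expect_equal(cm["1", "Y"], 1L)
  expect_equal(cm["2", "Y"], 1L)
  # unassigned molecules contribute nowhere; totals are conserved
  expect_equal(sum(cm), sum(assign %in% c(1L, 2L)))
  # dropping a cell drops its counts
  cm1 <- count_matrix(assign, tt, cells = 1L)
  expect_equal(sum(cm1), 4L)
})

test_that("count_matrix conserves transcripts on synthetic tissue", {
  tis <- small_tissue()
  tx <- filter_transcripts(tis$transcripts)
  a <- assign_transcripts(tis$cell_mask, tx)
  cells <- mask_labels(tis$cell_mask)
  cm <- count_matrix(a, tx, cells)
  expect_equal(sum(cm), sum(a > 0L))
  # per-gene column sums never exceed the gene's molecule count
  expect_true(all(colSums(cm) <= table(factor(tx$gene, colnames(cm)))))
})

test_that("cluster_cells recovers planted types at the target k", {
  pl <- planted_counts(K = 10, n_per = 100, seed = 23)
  lab <- cluster_cells(pl$counts, target_k = 10, seed = 1)
  expect_equal(attr(lab, "k"), 10)
  expect_gt(agreement(pl$truth, lab)$ari, 0.9)
  # same seed -> identical labels
  lab2 <- cluster_cells(pl$counts, target_k = 10, seed = 1)
  expect_identical(as.integer(lab), as.integer(lab2))
})

test_that("duplicated pure profiles are recovered exactly", {
  K <- 6; G <- 12
  prof <- diag(K * 10)[rep(1:K, each = 20), 1:G] + 1L
  counts <- prof * 5L
  rownames(counts) <- seq_len(nrow(counts))
  lab <- cluster_cells(counts, target_k = K, seed = 2, knn_k = 10)
  expect_equal(attr(lab, "k"), K)
  expect_equal(agreement(rep(1:K, each = 20), lab)$ari, 1)
})

test_that("cluster_cells reports an unattainable target with its trace", {
  pl <- planted_counts(K = 3, n_per = 40, seed = 24)
  expect_error(cluster_cells(pl$counts, target_k = 20, seed = 1),
               "resolution trace")
  expect_error(cluster_cells(pl$counts[1:5, ], target_k = 10), "fewer cells")
})

test_that("agreement metrics hit their analytic anchors", {
  x <- rep(1:4, each = 25)
  ag <- agreement(x, x)
  expect_equal(ag$ari, 1)
  expect_equal(ag$ami, 1)
  expect_equal(ag$homogeneity, 1)
  expect_equal(ag$completeness, 1)

  # one cluster against several true classes: homogeneity 0, completeness 1
  one <- rep(1, 100)
  ag2 <- agreement(x, one)
  expect_equal(ag2$homogeneity, 0)
  expect_equal(ag2$completeness, 1)

  # random labelings have ARI near 0
  set.seed(25)
  aris <- replicate(20, agreement(sample(1:5, 200, TRUE),
                                  sample(1:5, 200, TRUE))$ari)
  expect_lt(max(abs(aris)), 0.05)
})

test_that("agreement matches independent oracles on random labelings", {
  set.seed(26)
  for (i in 1:30) {
    n <- sample(30:150, 1)
    a <- sample(1:sample(2:6, 1), n, replace = TRUE)
    b <- sample(1:sample(2:6, 1), n, replace = TRUE)
    ag <- agreement(a, b)
    # ARI against mclust
    expect_equal(ag$ari, mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    # homogeneity/completeness from first-principles entropies
    tab <- table(a, b)
    H <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log(p)) }
    ha <- H(rowSums(tab)); hb <- H(colSums(tab))
    hab <- -sum((tab / n)[tab > 0] * log((tab / n)[tab > 0]))
    h_cond_a <- hab - hb  # H(a|b)
    h_cond_b <- hab - ha
    expect_equal(ag$homogeneity, if (ha == 0) 1 else 1 - h_cond_a / ha,
                 tolerance = 1e-12)
    expect_equal(ag$completeness, if (hb == 0) 1 else 1 - h_cond_b / hb,
                 tolerance = 1e-12)
    # symmetry properties
    ag_sw <- agreement(b, a)
    expect_equal(ag$ari, ag_sw$ari, tolerance = 1e-12)
    expect_equal(ag$ami, ag_sw$ami, tolerance = 1e-12)
    expect_equal(ag$homogeneity, ag_sw$completeness, tolerance = 1e-12)
    # AMI of identical labelings is 1; AMI bounded by 1
    expect_lte(ag$ami, 1 + 1e-12)
  }
})

test_that("AMI matches the exact hypergeometric expectation formula", {
  # hand-checkable 2x2 case computed against an independent direct sum
  a <- c(1, 1, 1, 2, 2, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 2, 1, 1)
  ag <- agreement(a, b)
  # independent recomputation (plain loops, no shared code)
  n <- 8; tab <- table(a, b)
  ai <- rowSums(tab); bj <- colSums(tab)
  mi <- 0
  for (i in 1:2) for (j in 1:2) if (tab[i, j] > 0)
    mi <- mi + tab[i, j] / n * log(n * tab[i, j] / (ai[i] * bj[j]))
  emi <- 0
  for (i in 1:2) for (j in 1:2) {
    for (nij in max(1, ai[i] + bj[j] - n):min(ai[i], bj[j])) {
      p <- exp(lchoose(bj[j], nij) + lchoose(n - bj[j], ai[i] - nij) -
                 lchoose(n, ai[i]))
      emi <- emi + p * nij / n * log(n * nij / (ai[i] * bj[j]))
    }
  }
  H <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log(p)) }
  want <- (mi - emi) / ((H(ai) + H(bj)) / 2 - emi)
  expect_equal(ag$ami, unname(want), tolerance = 1e-12)
})

test_that("morphology embedding separates distinct shape populations", {
  set.seed(27)
  n <- 80
  # elongated vs round populations in feature space
  f1 <- cbind(area = rnorm(n, 50, 5), aspect_ratio = rnorm(n, 3, 0.2),
              roundness = rnorm(n, 0.3, 0.03))
  f2 <- cbind(area = rnorm(n, 50, 5), aspect_ratio = rnorm(n, 1.05, 0.05),
              roundness = rnorm(n, 0.9, 0.03))
  feats <- rbind(f1, f2)
  types <- rep(c("spindle", "round"), each = n)
  emb <- morpho_embed(feats, types, seed = 3)
  expect_equal(dim(emb$embedding), c(2 * n, 2))
  cent <- emb$centroids
  expect_equal(nrow(cent), 2)
  sep <- sqrt(sum((cent$x[1] - cent$x[2]) ^ 2 + (cent$y[1] - cent$y[2]) ^ 2))
  spread <- mean(vapply(c("spindle", "round"), function(t) {
    e <- emb$embedding[types == t, ]
    mean(sqrt(rowSums(sweep(e, 2, colMeans(e)) ^ 2)))
  }, numeric(1)))
  expect_gt(sep, spread)

  # duplicated dataset labels yield coinciding centroids
  emb2 <- morpho_embed(rbind(feats, feats), rep(types, 2),
                       dataset = rep(c("d1", "d2"), each = 2 * n), seed = 3)
  c2 <- emb2$centroids
  type_sep <- sqrt(sum((colMeans(c2[c2$type == "spindle", c("x", "y")]) -
                          colMeans(c2[c2$type == "round", c("x", "y")])) ^ 2))
  for (t in c("spindle", "round")) {
    ct <- c2[c2$type == t, ]
    # duplicates land (stochastically) on top of each other: the two
    # dataset centroids of the same population nearly coincide relative
    # to the between-type separation
    dup_d <- sqrt((ct$x[1] - ct$x[2]) ^ 2 + (ct$y[1] - ct$y[2]) ^ 2)
    expect_lt(dup_d, 0.05 * type_sep)
  }

  # constant features are dropped with a warning
  expect_warning(
    morpho_embed(cbind(feats, flat = 1), types, seed = 3), "constant")
})

test_that("z-scored features have mean 0 and sd 1", {
  set.seed(28)
  x <- matrix(rnorm(300, 10, 4), ncol = 3)
  z <- scale(x)
  expect_equal(colMeans(z), rep(0, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(z, 2, sd), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("classification_report reproduces hand-computed metrics", {
  # 2-class worked example: TP1=1, FP1=0, FN1=1, TP2=2
  truth <- factor(c("A", "A", "B", "B"), levels = c("A", "B"))
  pred <- factor(c("A", "B", "B", "B"), levels = c("A", "B"))
  r <- classification_report(truth, pred)
  expect_equal(r$accuracy, 3 / 4)
  expect_equal(r$per_class$f1, c(2 / 3, 0.8))
  expect_equal(r$macro_f1, 11 / 15)

  # perfect predictions
  rp <- classification_report(truth, truth,
                              prob = cbind(A = c(1, 1, 0, 0),
                                           B = c(0, 0, 1, 1)))
  expect_equal(rp$accuracy, 1)
  expect_equal(rp$macro_f1, 1)
  expect_equal(rp$macro_auc, 1)
})

test_that("metric functions match brute-force oracles on random predictions", {
  set.seed(29)
  for (i in 1:100) {
    K <- sample(2:5, 1); n <- sample(20:80, 1)
    lev <- LETTERS[1:K]
    truth <- factor(sample(lev, n, replace = TRUE), levels = lev)
    prob <- matrix(rgamma(n * K, 1), n, K, dimnames = list(NULL, lev))
    prob <- prob / rowSums(prob)
    pred <- factor(lev[max.col(prob)], levels = lev)
    r <- classification_report(truth, pred, prob)
    # brute-force accuracy and per-class F1
    expect_equal(r$accuracy, mean(truth == pred))
    f1s <- aucs <- numeric(0)
    for (k in lev) {
      if (sum(truth == k) == 0) next
      tp <- sum(truth == k & pred == k)
      fp <- sum(truth != k & pred == k)
      fn <- sum(truth == k & pred != k)
      f1s <- c(f1s, if (2 * tp + fp + fn == 0) 0 else
        2 * tp / (2 * tp + fp + fn))
      # trapezoidal one-vs-rest AUC via explicit threshold sweep
      sc <- prob[, k]; y <- truth == k
      if (all(y) || !any(y)) { aucs <- c(aucs, NA) ; next }
      ths <- sort(unique(c(-Inf, sc, Inf)), decreasing = TRUE)
      tpr <- vapply(ths, function(t) mean(sc[y] >= t), numeric(1))
      fpr <- vapply(ths, function(t) mean(sc[!y] >= t), numeric(1))
      aucs <- c(aucs, sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2))
    }
    expect_equal(r$macro_f1, mean(f1s), tolerance = 1e-12)
    expect_equal(r$macro_auc, mean(aucs), tolerance = 1e-9)
  }
})

test_that("roc_auc agrees with pROC and handles ties", {
  set.seed(30)
  for (i in 1:20) {
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(60) + y, 1)  # rounding forces ties
    expect_equal(roc_auc(y == 1, s),
                 suppressMessages(as.numeric(pROC::auc(y, s,
                                                       direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("rf_evaluate aces linearly separable morphology", {
  set.seed(31)
  n <- 60
  types <- rep(paste0("t", 1:5), each = n)
  centers <- seq(0, 40, length.out = 5)
  feats <- data.frame(
    f1 = rnorm(5 * n, rep(centers, each = n), 0.5),
    f2 = rnorm(5 * n, rep(rev(centers), each = n), 0.5))
  r <- rf_evaluate(feats, types, seed = 4)
  expect_gt(r$accuracy, 0.95)
  expect_gt(r$macro_f1, 0.95)
  expect_gt(r$macro_auc, 0.95)
  expect_equal(r$K, 5)
  # unknown/unassigned cells are excluded before fitting
  types2 <- c(types, rep("unknown", 10))
  feats2 <- rbind(feats, feats[1:10, ])
  r2 <- rf_evaluate(feats2, types2, seed = 4)
  expect_equal(r2$n_train + r2$n_test, 5 * n)
})
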