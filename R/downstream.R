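#' Cell-by-gene count matrix from a transcript assignment
#'
#' Entry `(c, g)` counts the transcripts of gene `g` assigned to cell `c`.
#' Unassigned transcripts (label 0) contribute nowhere; cells outside
#' `cells` are dropped (pass the aligned cell set to restrict the matrix
#' to cells with a ground-truth correspondence).
#'
#' @param assignment Integer vector from [assign_transcripts()].
#' @param transcripts The [transcript_table()] the assignment was derived
#'   from.
#' @param cells Integer vector of cell labels to retain (rows, in this
#'   order).
#' @param genes Optional gene universe (columns); defaults to the sorted
#'   genes present in `transcripts`.
#' @return Integer matrix, `length(cells)` x `length(genes)`, with
#'   dimnames.
#' @export
count_matrix <- function(assignment, transcripts, cells,
                         genes = sort(unique(transcripts$gene))) {
  validate_transcripts(transcripts)
  if (length(assignment) != nrow(transcripts))
    stop("assignment length does not match the transcript table")
  cells <- as.integer(cells)
  keep <- assignment %in% cells[cells > 0L]
  tab <- table(factor(assignment[keep], levels = cells),
               factor(transcripts$gene[keep], levels = genes))
  m <- matrix(as.integer(tab), length(cells), length(genes),
              dimnames = list(cell = as.character(cells), gene = genes))
  m
}

#' Leiden clustering tuned to a target number of clusters
#'
#' The standard expression pipeline: library-size normalization to the
#' median library, `log1p`, PCA (up to `n_pcs` components), a k-nearest
#' neighbour graph in PC space and Leiden community detection, with the
#' resolution parameter tuned by bisection to reach `target_k` clusters.
#' Every `(resolution, k)` pair evaluated is cached; if `target_k` is not
#' attained within `max_evals` evaluations the closest cached relaxation is
#' accepted in the order `target_k`, then `target_k ± 1`, then
#' `target_k ± 2`.  Anything further raises an error carrying the
#' resolution trace.
#'
#' @param counts Cell-by-gene count matrix ([count_matrix()]).
#' @param target_k Desired number of clusters (default 10).
#' @param seed Integer seed (graph clustering randomness).
#' @param n_pcs Maximum number of principal components (default 50).
#' @param knn_k Neighbours in the kNN graph (default 15).
#' @param resolution_range Bisection interval for the Leiden resolution.
#' @param max_evals Maximum Leiden evaluations (default 40).
#' @return Integer cluster labels named by cell; attributes `k`,
#'   `resolution` and `trace` (data frame of evaluated pairs).
#' @export
cluster_cells <- function(counts, target_k = 10, seed = 1L, n_pcs = 50,
                          knn_k = 15,
                          resolution_range = c(0.01, 3), max_evals = 40) {
  if (nrow(counts) < target_k)
    stop("fewer cells than target clusters")
  if (ncol(counts) < 2L) stop("need at least 2 genes")
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  norm <- log1p(counts / lib * stats::median(lib[lib > 0]))
  npc <- min(n_pcs, ncol(norm) - 1L, nrow(norm) - 1L)
  pcs <- stats::prcomp(norm, center = TRUE, scale. = FALSE,
                       rank. = npc)$x
  g <- knn_graph(pcs, knn_k)

  run_leiden <- function(res) {
    memb <- with_seed(seed, igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res,
      n_iterations = 3)))
    as.integer(memb)
  }
  trace <- data.frame(resolution = numeric(), k = integer())
  cache <- list()
  evaluate <- function(res) {
    memb <- run_leiden(res)
    k <- length(unique(memb))
    trace[nrow(trace) + 1L, ] <<- list(res, k)
    cache[[length(cache) + 1L]] <<- list(resolution = res, k = k,
                                         membership = memb)
    list(k = k, membership = memb)
  }
  lo <- resolution_range[1]; hi <- resolution_range[2]
  rlo <- evaluate(lo); rhi <- evaluate(hi)
  n_eval <- 2L
  # cluster count grows (approximately) with resolution; bisect
  while (n_eval < max_evals) {
    hit <- Find(function(e) e$k == target_k, cache)
    if (!is.null(hit)) break
    mid <- (lo + hi) / 2
    rmid <- evaluate(mid)
    n_eval <- n_eval + 1L
    if (rmid$k < target_k) {
      lo <- mid; rlo <- rmid
    } else {
      hi <- mid; rhi <- rmid
    }
    if (hi - lo < 1e-6) break
  }
  for (dk in 0:2) {
    ks <- unique(c(target_k - dk, target_k + dk))
    hit <- Find(function(e) e$k %in% ks, cache)
    if (!is.null(hit)) {
      labels <- stats::setNames(hit$membership, rownames(counts))
      attr(labels, "k") <- hit$k
      attr(labels, "resolution") <- hit$resolution
      attr(labels, "trace") <- trace
      return(labels)
    }
  }
  stop(sprintf(
    "could not reach %d clusters (closest: %s); resolution trace: %s",
    target_k, paste(sort(unique(trace$k)), collapse = ","),
    paste(sprintf("%.3g->%d", trace$resolution, trace$k), collapse = " ")))
}

# undirected kNN graph (union of directed kNN edges) on rows of x
knn_graph <- function(x, k) {
  n <- nrow(x)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(x))
  edges <- matrix(0L, 0, 2)
  nb <- t(apply(d, 1, function(r) order(r)[2:(k + 1L)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Morphology UMAP embedding with per-dataset/type centroids
#'
#' Z-scores each feature across cells (constant features are dropped with
#' a warning), embeds with UMAP (Euclidean metric, `n_neighbors = 30`,
#' `min_dist = 0.01`) and computes centroids of the embedding for every
#' dataset-by-type combination.
#'
#' @param features Numeric matrix or data frame of per-cell morphology
#'   features (rows = cells).
#' @param types Cell-type label per cell.
#' @param dataset Dataset/tissue label per cell (default a single
#'   dataset).
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed Integer seed.
#' @return List with `embedding` (n x 2), `centroids` (data frame with
#'   dataset, type, x, y), `dropped` (constant feature names).
#' @export
morpho_embed <- function(features, types,
                         dataset = rep("dataset1", length(types)),
                         n_neighbors = 30, min_dist = 0.01, seed = 1L) {
  x <- as.matrix(as.data.frame(features)[
    vapply(as.data.frame(features), is.numeric, logical(1))])
  if (nrow(x) < n_neighbors)
    stop("need at least n_neighbors = ", n_neighbors, " cells")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning("dropping constant feature(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  z <- scale(x)
  emb <- with_seed(seed,
                   uwot::umap(z, n_neighbors = n_neighbors,
                              min_dist = min_dist, metric = "euclidean",
                              n_threads = 1))
  colnames(emb) <- c("x", "y")
  key <- interaction(dataset, types, drop = TRUE)
  cent <- do.call(rbind, lapply(levels(key), function(l) {
    sel <- key == l
    data.frame(dataset = dataset[sel][1], type = types[sel][1],
               x = mean(emb[sel, 1]), y = mean(emb[sel, 2]))
  }))
  list(embedding = emb, centroids = cent, dropped = dropped)
}

#' Morphology-based cell-type classification
#'
#' The evaluation protocol for asking whether shape alone separates cell
#' types: cells with missing/unknown labels are excluded, the analysis is
#' restricted to the `top_k` most abundant types, cells are split into
#' train/test with a stratified split (about `test_fraction` per class
#' held out), and a random forest (500 trees, class weights inversely
#' proportional to training class frequency) is fit on the numeric
#' features.  Metrics are computed on the held-out set with
#' [classification_report()].
#'
#' @param features Per-cell numeric features (matrix or data frame).
#' @param types Cell-type label per cell (`NA`, `"unknown"`,
#'   `"unassigned"` excluded).
#' @param top_k Number of most abundant classes retained (default 5).
#' @param test_fraction Held-out fraction per class (default 0.2).
#' @param n_trees Random forest size (default 500).
#' @param seed Integer seed (split and forest).
#' @return A [classification_report()] with extra fields `n_train` and
#'   `n_test`.
#' @export
rf_evaluate <- function(features, types, top_k = 5, test_fraction = 0.2,
                        n_trees = 500, seed = 1L) {
  x <- as.data.frame(features)
  x <- x[vapply(x, is.numeric, logical(1))]
  types <- as.character(types)
  ok <- !is.na(types) & !(tolower(types) %in% c("unknown", "unassigned"))
  x <- x[ok, , drop = FALSE]; types <- types[ok]
  tab <- sort(table(types), decreasing = TRUE)
  if (length(tab) < top_k)
    warning("only ", length(tab), " classes available (requested ", top_k, ")")
  keep_classes <- names(tab)[seq_len(min(top_k, length(tab)))]
  sel <- types %in% keep_classes
  x <- x[sel, , drop = FALSE]
  y <- factor(types[sel], levels = keep_classes)

  with_seed(seed, {
    test_idx <- unlist(lapply(keep_classes, function(k) {
      idx <- which(y == k)
      n_test <- max(1L, round(length(idx) * test_fraction))
      sample(idx, min(n_test, length(idx) - 1L))
    }))
    train_idx <- setdiff(seq_along(y), test_idx)
    freq <- table(y[train_idx])
    wt <- as.numeric(1 / freq)
    names(wt) <- names(freq)
    fit <- randomForest::randomForest(
      x = x[train_idx, , drop = FALSE], y = y[train_idx],
      ntree = n_trees, classwt = wt)
    prob <- stats::predict(fit, x[test_idx, , drop = FALSE], type = "prob")
    pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                   levels = levels(y))
    rep <- classification_report(y[test_idx], pred, prob)
    rep$n_train <- length(train_idx)
    rep$n_test <- length(test_idx)
    rep
  })
}
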