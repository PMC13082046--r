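# Independent brute-force oracles.  These deliberately use the most naive
# formulation available (double loops, all-pairs, exhaustive enumeration)
# and share no code with the implementation paths they check.

oracle_iou_matrix <- function(gt, pred) {
  gl <- sort(unique(gt[gt > 0]))
  pl <- sort(unique(pred[pred > 0]))
  out <- matrix(0, length(gl), length(pl))
  for (i in seq_along(gl)) {
    gi <- which(gt == gl[i])
    for (j in seq_along(pl)) {
      pj <- which(pred == pl[j])
      out[i, j] <- length(intersect(gi, pj)) / length(union(gi, pj))
    }
  }
  list(gt_labels = gl, pred_labels = pl, values = out)
}

oracle_gene_iou <- function(ga, pa) {
  gl <- sort(unique(ga[ga > 0]))
  pl <- sort(unique(pa[pa > 0]))
  per <- numeric(length(pl))
  for (j in seq_along(pl)) {
    Lj <- which(pa == pl[j])
    best <- 0
    for (i in seq_along(gl)) {
      Ki <- which(ga == gl[i])
      best <- max(best, length(intersect(Ki, Lj)) / length(union(Ki, Lj)))
    }
    per[j] <- best
  }
  list(per_pred = per, tile_mean = if (length(per)) mean(per) else NA_real_)
}

oracle_align <- function(values, gt_labels, pred_labels, threshold = 0.3) {
  pairs <- list()
  for (gi in seq_along(gt_labels)) {
    for (pj in seq_along(pred_labels)) {
      v <- values[gi, pj]
      if (v < threshold) next
      # mutual best with smaller-label tie-break
      row_best <- min(which(values[gi, ] == max(values[gi, ])))
      col_best <- min(which(values[, pj] == max(values[, pj])))
      if (row_best == pj && col_best == gi)
        pairs[[length(pairs) + 1L]] <- c(gt_labels[gi], pred_labels[pj])
    }
  }
  if (!length(pairs)) return(matrix(numeric(0), 0, 2))
  do.call(rbind, pairs)
}

# exhaustive nearest-nucleus expansion on a small label matrix
oracle_expand <- function(nuclei, rad_px) {
  H <- nrow(nuclei); W <- ncol(nuclei)
  out <- matrix(0L, H, W)
  nuc_px <- which(nuclei > 0, arr.ind = TRUE)
  nuc_lab <- nuclei[nuc_px]
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (nuclei[r, c] > 0) { out[r, c] <- nuclei[r, c]; next }
    d2 <- (nuc_px[, 1] - r) ^ 2 + (nuc_px[, 2] - c) ^ 2
    dmin <- min(d2)
    if (dmin <= rad_px ^ 2 + 1e-9)
      out[r, c] <- min(nuc_lab[d2 == dmin])
  }
  out
}

# trapezoid-rule polygon area (different formula than the shoelace used
# in the package)
oracle_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum((v[j, 1] - v[, 1]) * (v[j, 2] + v[, 2]) / 2))
}

oracle_perimeter <- function(v) {
  n <- nrow(v)
  tot <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    tot <- tot + sqrt((v[i, 1] - v[j, 1]) ^ 2 + (v[i, 2] - v[j, 2]) ^ 2)
  }
  tot
}

oracle_feret <- function(v) {
  best <- 0
  for (i in seq_len(nrow(v))) for (j in seq_len(nrow(v)))
    best <- max(best, sqrt(sum((v[i, ] - v[j, ]) ^ 2)))
  best
}

oracle_eccentricity <- function(v) {
  lam <- stats::prcomp(v)$sdev ^ 2
  1 - lam[2] / lam[1]
}

# exact minimum enclosing circle by enumerating all pair- and
# triple-defined circles (O(n^3); keep vertex counts small)
oracle_mec_radius <- function(v) {
  v <- unique(v)
  n <- nrow(v)
  covers <- function(ctr, r) all(sqrt((v[, 1] - ctr[1]) ^ 2 +
                                        (v[, 2] - ctr[2]) ^ 2) <= r + 1e-9)
  best <- Inf
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ctr <- (v[i, ] + v[j, ]) / 2
    r <- sqrt(sum((v[i, ] - v[j, ]) ^ 2)) / 2
    if (covers(ctr, r)) best <- min(best, r)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (k <= j || j <= i) next
    a <- v[i, ]; b <- v[j, ]; ccc <- v[k, ]
    d <- 2 * (a[1] * (b[2] - ccc[2]) + b[1] * (ccc[2] - a[2]) +
                ccc[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next
    ux <- (sum(a ^ 2) * (b[2] - ccc[2]) + sum(b ^ 2) * (ccc[2] - a[2]) +
             sum(ccc ^ 2) * (a[2] - b[2])) / d
    uy <- (sum(a ^ 2) * (ccc[1] - b[1]) + sum(b ^ 2) * (a[1] - ccc[1]) +
             sum(ccc ^ 2) * (b[1] - a[1])) / d
    r <- sqrt(sum((a - c(ux, uy)) ^ 2))
    if (covers(c(ux, uy), r)) best <- min(best, r)
  }
  best
}

# min-area bounding rectangle by checking every hull-edge direction
# (independent code path: hull via grDevices::chull, projections by
# rotation matrices)
oracle_min_rect_sides <- function(v) {
  h <- v[grDevices::chull(v), , drop = FALSE]
  n <- nrow(h)
  best <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ang <- atan2(h[j, 2] - h[i, 2], h[j, 1] - h[i, 1])
    R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2)
    rot <- h %*% t(R)
    w <- diff(range(rot[, 1])); ht <- diff(range(rot[, 2]))
    if (is.null(best) || w * ht < best$area)
      best <- list(area = w * ht, sides = sort(c(w, ht)))
  }
  best$sides
}

# all side pairs whose rectangle area ties the minimum (triangular hulls
# tie on every edge: base x height = 2 x triangle area)
oracle_min_rect_tied_sides <- function(v, tol = 1e-9) {
  h <- v[grDevices::chull(v), , drop = FALSE]
  n <- nrow(h)
  rects <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ang <- atan2(h[j, 2] - h[i, 2], h[j, 1] - h[i, 1])
    R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2)
    rot <- h %*% t(R)
    w <- diff(range(rot[, 1])); ht <- diff(range(rot[, 2]))
    rects[[i]] <- c(area = w * ht, sides = sort(c(w, ht)))
  }
  areas <- vapply(rects, `[[`, numeric(1), 1)
  amin <- min(areas)
  lapply(rects[areas <= amin * (1 + tol)], function(r) unname(r[2:3]))
}

# random simple (star-shaped) polygon around the origin
random_polygon <- function(n = 12, r_range = c(1, 4)) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_range[1], r_range[2])
  cbind(r * cos(th), r * sin(th))
}

random_convex_polygon <- function(n = 20, scale = 5) {
  pts <- matrix(stats::rnorm(n * 2, sd = scale), ncol = 2)
  pts[grDevices::chull(pts), , drop = FALSE]
}

# random small label mask with a few blobs (labels may be sparse)
random_label_matrix <- function(H = 24, W = 24, n_blobs = 4) {
  m <- matrix(0L, H, W)
  for (b in seq_len(n_blobs)) {
    r <- sample(H, 1); c <- sample(W, 1)
    rr <- max(1, r - sample(1:4, 1)):min(H, r + sample(1:4, 1))
    cc <- max(1, c - sample(1:4, 1)):min(W, c + sample(1:4, 1))
    m[rr, cc] <- b * sample(1:3, 1)
  }
  m
}
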