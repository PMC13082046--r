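# Planar geometry primitives for cell morphometrics.
# All functions take an n x 2 vertex matrix (implicitly closed polygon).

polygon_vertices <- function(p) {
  if (inherits(p, "cell_polygon")) p$vertices else as_xy_matrix(p)
}

# signed shoelace area (positive for counter-clockwise in a y-up frame;
# callers use abs())
shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

polygon_perimeter_of <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(sqrt(rowSums((v[j, , drop = FALSE] - v) ^ 2)))
}

# convex hull vertices in order (grDevices::chull), as a matrix
convex_hull <- function(v) {
  idx <- grDevices::chull(v[, 1], v[, 2])
  v[idx, , drop = FALSE]
}

# Exact minimum enclosing circle: Welzl's algorithm, iterative
# move-to-front variant.  Returns list(center = c(x, y), radius).
min_enclosing_circle <- function(pts) {
  pts <- unique(as_xy_matrix(pts))
  n <- nrow(pts)
  if (n == 0L) stop("no points")
  if (n == 1L) return(list(center = pts[1, ], radius = 0))
  circ2 <- function(a, b) {
    list(center = (a + b) / 2, radius = sqrt(sum((a - b) ^ 2)) / 2)
  }
  circ3 <- function(a, b, c) {
    # circumcircle; degenerate (collinear) handled by caller fallbacks
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-14) return(NULL)
    ux <- (sum(a ^ 2) * (b[2] - c[2]) + sum(b ^ 2) * (c[2] - a[2]) +
             sum(c ^ 2) * (a[2] - b[2])) / d
    uy <- (sum(a ^ 2) * (c[1] - b[1]) + sum(b ^ 2) * (a[1] - c[1]) +
             sum(c ^ 2) * (b[1] - a[1])) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((a - ctr) ^ 2)))
  }
  inside <- function(circ, p, tol = 1e-9) {
    !is.null(circ) &&
      sqrt(sum((p - circ$center) ^ 2)) <= circ$radius * (1 + tol) + 1e-12
  }
  # trivial circle for up to 3 boundary points
  trivial <- function(bnd) {
    k <- length(bnd)
    if (k == 0L) return(list(center = c(0, 0), radius = -1))
    if (k == 1L) return(list(center = bnd[[1]], radius = 0))
    if (k == 2L) return(circ2(bnd[[1]], bnd[[2]]))
    # try the three pairwise circles first (handles obtuse triangles)
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      c2 <- circ2(bnd[[pair[1]]], bnd[[pair[2]]])
      other <- bnd[[setdiff(1:3, pair)]]
      if (inside(c2, other)) return(c2)
    }
    c3 <- circ3(bnd[[1]], bnd[[2]], bnd[[3]])
    if (is.null(c3)) {
      # collinear: span the two farthest apart
      d <- as.matrix(stats::dist(do.call(rbind, bnd)))
      ij <- which(d == max(d), arr.ind = TRUE)[1, ]
      return(circ2(bnd[[ij[1]]], bnd[[ij[2]]]))
    }
    c3
  }
  welzl <- function(order, bnd) {
    circ <- trivial(bnd)
    if (length(bnd) == 3L) return(circ)
    for (i in seq_along(order)) {
      p <- pts[order[i], ]
      if (!inside(circ, p)) {
        circ <- welzl(order[seq_len(i - 1L)], c(bnd, list(p)))
      }
    }
    circ
  }
  # hull points suffice (the MEC is determined by hull points); a
  # deterministic interleaved order keeps the recursion shallow without
  # touching the RNG state
  pts <- convex_hull(pts)
  m <- nrow(pts)
  ord <- as.vector(rbind(seq_len(ceiling(m / 2)),
                         m + 1L - seq_len(ceiling(m / 2))))
  ord <- unique(ord[ord <= m])
  welzl(ord, list())
}

# Minimum-area rotated bounding rectangle via rotating calipers over hull
# edges: the optimal rectangle has one side collinear with a hull edge.
# Returns list(width, height, area, angle).
min_area_rect <- function(v) {
  h <- convex_hull(v)
  n <- nrow(h)
  if (n == 1L) return(list(width = 0, height = 0, area = 0, angle = 0))
  if (n == 2L) {
    len <- sqrt(sum((h[2, ] - h[1, ]) ^ 2))
    return(list(width = len, height = 0, area = 0,
                angle = atan2(h[2, 2] - h[1, 2], h[2, 1] - h[1, 1])))
  }
  best <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- h[j, ] - h[i, ]
    len <- sqrt(sum(e ^ 2))
    if (len < 1e-14) next
    ux <- e / len                 # edge direction
    uy <- c(-ux[2], ux[1])        # normal
    s <- h %*% cbind(ux, uy)
    w <- max(s[, 1]) - min(s[, 1])
    ht <- max(s[, 2]) - min(s[, 2])
    a <- w * ht
    if (is.null(best) || a < best$area)
      best <- list(width = w, height = ht, area = a,
                   angle = atan2(ux[2], ux[1]))
  }
  best
}

# Pixel-center point-in-polygon (mgcv::in.out); pts n x 2, vertices closed
# implicitly.  Boundary points are resolved arbitrarily by the crossing test.
points_in_polygon <- function(pts, v) {
  bnd <- rbind(v, v[1, , drop = FALSE])
  as.logical(mgcv::in.out(bnd, as_xy_matrix(pts)))
}
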