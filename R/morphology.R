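#' Trace the boundary polygon of a mask instance
#'
#' Traces the outer boundary of a (4-connected) instance along pixel
#' corners, so the polygon encloses exactly the instance's pixels and its
#' shoelace area equals `pixel count * pixel_size^2`.  Interior holes are
#' ignored (only the outer contour is returned).  At corners where the
#' boundary pinches diagonally the trace continues across the pinch, so the
#' contour stays a single loop (with a repeated corner vertex).  Collinear
#' intermediate vertices are dropped.
#'
#' @param mask A [label_mask()].
#' @param label Positive instance label present in the mask.
#' @return A [cell_polygon()] in global µm coordinates.
#' @export
polygon_from_mask <- function(mask, label) {
  stopifnot(inherits(mask, "label_mask"))
  sel <- which(mask$labels == label, arr.ind = TRUE)
  if (nrow(sel) == 0L) stop("label ", label, " is absent from the mask")
  r0 <- min(sel[, 1]); r1 <- max(sel[, 1])
  c0 <- min(sel[, 2]); c1 <- max(sel[, 2])
  # binary sub-image with a 1-pixel pad so every boundary edge has an
  # outside neighbor
  h <- r1 - r0 + 3L; w <- c1 - c0 + 3L
  bin <- matrix(FALSE, h, w)
  bin[cbind(sel[, 1] - r0 + 2L, sel[, 2] - c0 + 2L)] <- TRUE
  if (!instance_connected(bin))
    stop("label ", label, " is not 4-connected; cannot trace one boundary")

  inb <- which(bin, arr.ind = TRUE)
  # directed crack edges, instance kept on a consistent side:
  #   top    (r,c)   -> (r,c+1)    when (r-1,c) outside
  #   right  (r,c+1) -> (r+1,c+1)  when (r,c+1) outside
  #   bottom (r+1,c+1)->(r+1,c)    when (r+1,c) outside
  #   left   (r+1,c) -> (r,c)      when (r,c-1) outside
  out_at <- function(dr, dc) !bin[cbind(inb[, 1] + dr, inb[, 2] + dc)]
  e <- list()
  t_ <- out_at(-1L, 0L)
  e[[1]] <- cbind(inb[t_, 1], inb[t_, 2], inb[t_, 1], inb[t_, 2] + 1L)
  t_ <- out_at(0L, 1L)
  e[[2]] <- cbind(inb[t_, 1], inb[t_, 2] + 1L, inb[t_, 1] + 1L, inb[t_, 2] + 1L)
  t_ <- out_at(1L, 0L)
  e[[3]] <- cbind(inb[t_, 1] + 1L, inb[t_, 2] + 1L, inb[t_, 1] + 1L, inb[t_, 2])
  t_ <- out_at(0L, -1L)
  e[[4]] <- cbind(inb[t_, 1] + 1L, inb[t_, 2], inb[t_, 1], inb[t_, 2])
  edges <- do.call(rbind, e)

  key <- function(r, c) r * (w + 2L) + c
  loops <- trace_loops(edges, key(edges[, 1], edges[, 2]),
                       key(edges[, 3], edges[, 4]))
  # outer contour = loop of maximal |area| (holes are traced too but are
  # strictly smaller)
  areas <- vapply(loops, function(v) abs(shoelace_area(v)), numeric(1))
  loop <- loops[[which.max(areas)]]
  loop <- drop_collinear(loop)
  # corner (r, c) -> global µm of that pixel corner
  s <- mask$frame$pixel_size
  xy <- cbind(mask$frame$origin[1] + (loop[, 2] + c0 - 2L - 1L) * s,
              mask$frame$origin[2] + (loop[, 1] + r0 - 2L - 1L) * s)
  cell_polygon(xy, label)
}

# 4-connectivity check by flood fill on a padded logical matrix
instance_connected <- function(bin) {
  n <- sum(bin)
  if (n <= 1L) return(TRUE)
  start <- which(bin)[1]
  h <- nrow(bin)
  seen <- logical(length(bin))
  stack <- start
  seen[start] <- TRUE
  count <- 0L
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    count <- count + 1L
    for (d in c(-1L, 1L, -h, h)) {
      j <- i + d
      if (j >= 1L && j <= length(bin) && bin[j] && !seen[j]) {
        seen[j] <- TRUE
        stack <- c(stack, j)
      }
    }
  }
  count == n
}

# chain directed crack edges into closed loops; at corners with two
# outgoing edges prefer the clockwise (most negative cross product) turn,
# which carries the trace across diagonal pinches instead of splitting the
# loop
trace_loops <- function(edges, from, to) {
  ord <- order(from)
  edges <- edges[ord, , drop = FALSE]
  from <- from[ord]
  to <- to[ord]
  n <- nrow(edges)
  used <- logical(n)
  find_out <- function(k) {
    i <- findInterval(k - 1L, from) + 1L
    idx <- integer()
    while (i <= n && from[i] == k) {
      if (!used[i]) idx <- c(idx, i)
      i <- i + 1L
    }
    idx
  }
  loops <- list()
  for (start in seq_len(n)) {
    if (used[start]) next
    cur <- start
    pts <- edges[start, 1:2, drop = FALSE]
    repeat {
      used[cur] <- TRUE
      cand <- find_out(to[cur])
      if (!length(cand)) break  # loop closed (back at the used start edge)
      if (length(cand) > 1L) {
        din <- edges[cur, 3:4] - edges[cur, 1:2]
        crosses <- vapply(cand, function(j) {
          dout <- edges[j, 3:4] - edges[j, 1:2]
          # cross product in screen coords (x = col, y = row)
          din[2] * dout[1] - din[1] * dout[2]
        }, numeric(1))
        cur <- cand[which.min(crosses)]
      } else cur <- cand
      pts <- rbind(pts, edges[cur, 1:2])
    }
    loops[[length(loops) + 1L]] <- pts
  }
  loops
}

drop_collinear <- function(v) {
  n <- nrow(v)
  if (n <= 3L) return(v)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- v[if (i == 1L) n else i - 1L, ]
    q <- v[i, ]
    r <- v[if (i == n) 1L else i + 1L, ]
    keep[i] <- abs((q[1] - p[1]) * (r[2] - p[2]) -
                     (q[2] - p[2]) * (r[1] - p[1])) > 1e-12
  }
  if (!any(keep)) return(v)
  v[keep, , drop = FALSE]
}

#' Polygon-based morphological features
#'
#' The eight per-cell shape descriptors computed from a boundary polygon:
#'
#' * `polygon_area()` — shoelace area (µm²).
#' * `polygon_perimeter()` — closed polyline length (µm).
#' * `feret_diameter()` — maximum pairwise distance between convex-hull
#'   points (µm); attained at hull vertices.
#' * `eccentricity()` — `1 - lambda2/lambda1` from a PCA of the raw vertex
#'   coordinates, where `lambda1 >= lambda2` are the component variances.
#'   0 for isotropic vertex clouds, approaching 1 for elongated ones;
#'   exactly 1 when vertices are collinear.
#' * `roundness()` — area over the area of the exact minimum enclosing
#'   circle of the vertices.
#' * `circularity()` — `4 * pi * A / P^2`; 1 for a circle.
#' * `solidity()` — area over convex-hull area; 1 for convex polygons.
#' * `aspect_ratio()` — long/short side ratio (>= 1) of the minimum-area
#'   rotated bounding rectangle (rotating calipers).
#'
#' @param p A [cell_polygon()] or an n x 2 vertex matrix.
#' @return A single numeric value; [compute_features()] returns a one-row
#'   data frame with all eight.
#' @name morphology_features
NULL

#' @rdname morphology_features
#' @export
polygon_area <- function(p) {
  v <- polygon_vertices(p)
  a <- abs(shoelace_area(v))
  if (a <= 0) stop("degenerate polygon: zero area")
  a
}

#' @rdname morphology_features
#' @export
polygon_perimeter <- function(p) polygon_perimeter_of(polygon_vertices(p))

#' @rdname morphology_features
#' @export
feret_diameter <- function(p) {
  v <- unique(polygon_vertices(p))
  if (nrow(v) < 2L) stop("Feret diameter needs at least 2 distinct vertices")
  h <- convex_hull(v)
  sqrt(max(stats::dist(h) ^ 2))
}

#' @rdname morphology_features
#' @export
eccentricity <- function(p) {
  v <- polygon_vertices(p)
  ev <- sort(eigen(stats::cov(v), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  l1 <- max(ev[1], 0); l2 <- max(ev[2], 0)
  if (l1 <= 0) stop("degenerate polygon: all vertices coincide")
  1 - l2 / l1
}

#' @rdname morphology_features
#' @export
roundness <- function(p) {
  v <- polygon_vertices(p)
  circ <- min_enclosing_circle(v)
  polygon_area(v) / (pi * circ$radius ^ 2)
}

#' @rdname morphology_features
#' @export
circularity <- function(p) {
  v <- polygon_vertices(p)
  4 * pi * polygon_area(v) / polygon_perimeter_of(v) ^ 2
}

#' @rdname morphology_features
#' @export
solidity <- function(p) {
  v <- polygon_vertices(p)
  polygon_area(v) / abs(shoelace_area(convex_hull(v)))
}

#' @rdname morphology_features
#' @export
aspect_ratio <- function(p) {
  v <- polygon_vertices(p)
  r <- min_area_rect(v)
  lo <- min(r$width, r$height)
  if (lo <= 1e-12) stop("degenerate polygon: zero-width bounding rectangle")
  max(r$width, r$height) / lo
}

#' @rdname morphology_features
#' @export
compute_features <- function(p) {
  v <- polygon_vertices(p)
  data.frame(area = polygon_area(v),
             perimeter = polygon_perimeter(v),
             feret = feret_diameter(v),
             eccentricity = eccentricity(v),
             roundness = roundness(v),
             circularity = circularity(v),
             solidity = solidity(v),
             aspect_ratio = aspect_ratio(v))
}

#' Morphological features for every instance in a mask
#'
#' Traces each instance's boundary polygon with [polygon_from_mask()] and
#' computes the eight descriptors.
#'
#' @param mask A [label_mask()].
#' @return Data frame with a `label` column plus the eight feature columns,
#'   one row per instance.
#' @export
features_from_mask <- function(mask) {
  labs <- mask_labels(mask)
  rows <- lapply(labs, function(l)
    cbind(label = l, compute_features(polygon_from_mask(mask, l))))
  if (!length(rows))
    return(data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), feret = numeric(),
                      eccentricity = numeric(), roundness = numeric(),
                      circularity = numeric(), solidity = numeric(),
                      aspect_ratio = numeric()))
  do.call(rbind, rows)
}
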