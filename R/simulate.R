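#' Parameters of the synthetic tissue generator
#'
#' Defaults describe a desk-scale tissue patch that reproduces the
#' qualitative regime whole-cell segmentation is evaluated in: contiguous,
#' non-circular cells of varied elongation; nuclei clearly smaller than and
#' off-centre within their cells; the large majority of transcripts falling
#' inside cell boundaries; and a low-quality background molecule
#' population that the quality filter is meant to remove.
#'
#' @param n_cells Number of cells to place.
#' @param frame A [pixel_frame()]; default 384 x 384 px at 0.5 µm/px
#'   (a 192 µm square patch).
#' @param n_types Number of cell types (distinct morphology and expression
#'   profiles).
#' @param mean_cell_radius Mean equivalent cell radius in µm.
#' @param cell_elongation_range Range of per-cell axis ratios (>= 1).
#' @param nucleus_area_fraction Nucleus area as a fraction of cell area.
#' @param nucleus_offset_fraction Nucleus centre offset as a fraction of
#'   the local cell radius, in a random direction.
#' @param transcripts_per_cell_mean Poisson mean of per-cell molecule
#'   counts.
#' @param background_transcript_rate Background molecules per µm².
#' @param n_genes Panel size.
#' @param profile_concentration Dirichlet concentration of per-type gene
#'   profiles (< 1 gives sparse, well-separated profiles).
#' @param dapi_noise_sd Gaussian noise added to the rendered DAPI image.
#' @param seed Integer seed; the whole tissue is reproducible from it.
#' @return A `simulation_params` object.
#' @export
simulation_params <- function(n_cells = 120,
                              frame = pixel_frame(384, 384, 0.5),
                              n_types = 5,
                              mean_cell_radius = 7,
                              cell_elongation_range = c(1, 3),
                              nucleus_area_fraction = 0.35,
                              nucleus_offset_fraction = 0.3,
                              transcripts_per_cell_mean = 80,
                              background_transcript_rate = 0.05,
                              n_genes = 50,
                              profile_concentration = 0.3,
                              dapi_noise_sd = 0.05,
                              seed = 1L) {
  assert_frame(frame)
  stopifnot(n_cells >= 1, n_types >= 1, mean_cell_radius > 0,
            length(cell_elongation_range) == 2L,
            cell_elongation_range[1] >= 1,
            diff(cell_elongation_range) >= 0,
            nucleus_area_fraction > 0, nucleus_area_fraction < 1,
            nucleus_offset_fraction >= 0, nucleus_offset_fraction < 1,
            transcripts_per_cell_mean > 0,
            background_transcript_rate >= 0,
            n_genes >= 1, profile_concentration > 0, dapi_noise_sd >= 0)
  structure(as.list(environment()), class = "simulation_params")
}

#' Simulate a tissue with known whole-cell ground truth
#'
#' Cells are grown from blue-noise seed points as perturbed anisotropic
#' metric balls: each pixel joins the cell whose stretched, wobbled
#' normalized distance is smallest and at most 1, which yields contiguous,
#' space-partitioning, non-circular instances (each cell is cleaned to its
#' largest 4-connected component).  Nuclei are ellipses with
#' `nucleus_area_fraction` of the cell area, offset from the cell centroid
#' by `nucleus_offset_fraction` of the local radius in a random direction
#' and clipped to the cell.  Per-cell transcript counts are Poisson;
#' positions are uniform over the cell's pixel set (so every cell molecule
#' lies inside its cell's mask); genes follow the cell type's profile and
#' quality scores are high (>= 20).  Background molecules arrive as a
#' spatial Poisson process over the frame with mostly sub-20 quality
#' scores.  DAPI is the rendered nucleus image with per-nucleus brightness,
#' Gaussian blur and clipped Gaussian noise.
#'
#' @param params A [simulation_params()].
#' @return A `synthetic_tissue`: list with `cell_mask`, `nucleus_mask`,
#'   `cell_polygons`, `cell_types`, `transcripts` (with a ground-truth
#'   `cell` column, 0 = background), `dapi`, `gene_profiles` and `params`.
#' @export
simulate_tissue <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, simulate_tissue_impl(params))
}

simulate_tissue_impl <- function(p) {
  fr <- p$frame
  s <- fr$pixel_size
  H <- fr$height; W <- fr$width
  wd <- W * s; ht <- H * s

  # --- blue-noise seed points (dart throwing) ---
  min_sep <- 1.5 * p$mean_cell_radius
  margin <- 0.5 * p$mean_cell_radius
  if (wd - 2 * margin <= 0 || ht - 2 * margin <= 0)
    stop("packing error: frame too small for the requested cell radius")
  seeds <- matrix(NA_real_, p$n_cells, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 1000L * p$n_cells
  while (placed < p$n_cells && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- c(stats::runif(1, margin, wd - margin) + fr$origin[1],
              stats::runif(1, margin, ht - margin) + fr$origin[2])
    if (placed == 0L ||
        min(sqrt(rowSums((seeds[seq_len(placed), , drop = FALSE] -
                            matrix(cand, placed, 2, byrow = TRUE)) ^ 2))) >=
        min_sep) {
      placed <- placed + 1L
      seeds[placed, ] <- cand
    }
  }
  if (placed < p$n_cells)
    stop(sprintf(
      "packing error: placed only %d of %d cells at mean radius %g µm",
      placed, p$n_cells, p$mean_cell_radius))

  # --- per-type and per-cell morphology / expression parameters ---
  type_size <- stats::runif(p$n_types, 0.85, 1.15)
  type_elong <- stats::runif(p$n_types, p$cell_elongation_range[1],
                             p$cell_elongation_range[2])
  profiles <- matrix(stats::rgamma(p$n_types * p$n_genes,
                                   shape = p$profile_concentration),
                     p$n_types, p$n_genes)
  profiles <- profiles / rowSums(profiles)
  rownames(profiles) <- paste0("type", seq_len(p$n_types))
  colnames(profiles) <- sprintf("gene%03d", seq_len(p$n_genes))

  ctype <- sample.int(p$n_types, p$n_cells, replace = TRUE)
  radius <- p$mean_cell_radius * type_size[ctype] *
    exp(stats::rnorm(p$n_cells, 0, 0.12))
  elong <- pmax(1, type_elong[ctype] * exp(stats::rnorm(p$n_cells, 0, 0.08)))
  theta <- stats::runif(p$n_cells, 0, pi)
  wob_amp <- stats::runif(p$n_cells, 0.03, 0.10)
  wob_k <- sample(2:5, p$n_cells, replace = TRUE)
  wob_ph <- stats::runif(p$n_cells, 0, 2 * pi)

  # --- pixel assignment: perturbed anisotropic nearest-seed ---
  grid <- pixel_center_grid(fr)
  best_d <- matrix(Inf, H, W)
  best_l <- matrix(0L, H, W)
  for (i in seq_len(p$n_cells)) {
    a <- radius[i] * sqrt(elong[i])
    b <- radius[i] / sqrt(elong[i])
    reach <- a * (1 + wob_amp[i]) + s
    cols <- which(abs(grid$x - seeds[i, 1]) <= reach)
    rows <- which(abs(grid$y - seeds[i, 2]) <= reach)
    if (!length(rows) || !length(cols)) next
    dx <- matrix(grid$x[cols] - seeds[i, 1], length(rows), length(cols),
                 byrow = TRUE)
    dy <- matrix(grid$y[rows] - seeds[i, 2], length(rows), length(cols))
    u <- dx * cos(theta[i]) + dy * sin(theta[i])
    v <- -dx * sin(theta[i]) + dy * cos(theta[i])
    d <- sqrt((u / a) ^ 2 + (v / b) ^ 2) /
      (1 + wob_amp[i] * sin(wob_k[i] * atan2(v, u) + wob_ph[i]))
    upd <- d <= 1 & d < best_d[rows, cols]
    sub_l <- best_l[rows, cols]; sub_d <- best_d[rows, cols]
    sub_l[upd] <- i; sub_d[upd] <- d[upd]
    best_l[rows, cols] <- sub_l; best_d[rows, cols] <- sub_d
  }

  # --- connectivity cleanup and relabeling ---
  best_l <- keep_largest_component(best_l)
  sizes <- tabulate(best_l[best_l > 0L], nbins = p$n_cells)
  kept <- which(sizes >= 12L)
  newlab <- integer(p$n_cells)
  newlab[kept] <- seq_along(kept)
  lab <- matrix(0L, H, W)
  nz <- best_l > 0L
  lab[nz] <- newlab[best_l[nz]]
  cell_mask <- label_mask(lab, fr)
  n_kept <- length(kept)
  if (n_kept == 0L) stop("packing error: no cells survived rasterization")

  cell_types <- stats::setNames(ctype[kept], seq_len(n_kept))

  # --- nuclei: offset ellipses clipped to their cells ---
  nuc <- matrix(0L, H, W)
  nuc_dir <- stats::runif(n_kept, 0, 2 * pi)
  for (j in seq_len(n_kept)) {
    i <- kept[j]
    px <- which(lab == j, arr.ind = TRUE)
    cx <- mean(grid$x[px[, 2]]); cy <- mean(grid$y[px[, 1]])
    area_c <- nrow(px) * s ^ 2
    r_local <- sqrt(area_c / pi)
    ctr <- c(cx, cy) + p$nucleus_offset_fraction * r_local *
      c(cos(nuc_dir[j]), sin(nuc_dir[j]))
    e_n <- sqrt(elong[i])
    a_n <- sqrt(p$nucleus_area_fraction * area_c * e_n / pi)
    b_n <- sqrt(p$nucleus_area_fraction * area_c / (pi * e_n))
    dx <- grid$x[px[, 2]] - ctr[1]
    dy <- grid$y[px[, 1]] - ctr[2]
    u <- dx * cos(theta[i]) + dy * sin(theta[i])
    v <- -dx * sin(theta[i]) + dy * cos(theta[i])
    inside <- (u / a_n) ^ 2 + (v / b_n) ^ 2 <= 1
    if (!any(inside)) {
      # fully clipped: recentre the nucleus on the cell centroid
      dx <- grid$x[px[, 2]] - cx; dy <- grid$y[px[, 1]] - cy
      u <- dx * cos(theta[i]) + dy * sin(theta[i])
      v <- -dx * sin(theta[i]) + dy * cos(theta[i])
      inside <- (u / a_n) ^ 2 + (v / b_n) ^ 2 <= 1
      if (!any(inside)) inside <- seq_len(nrow(px)) == 1L
    }
    nuc[px[inside, , drop = FALSE]] <- j
  }
  nucleus_mask <- label_mask(nuc, fr)

  # --- transcripts ---
  counts <- stats::rpois(n_kept, p$transcripts_per_cell_mean)
  tx_list <- vector("list", n_kept + 1L)
  for (j in seq_len(n_kept)) {
    n_t <- counts[j]
    if (n_t == 0L) next
    px <- which(lab == j, arr.ind = TRUE)
    pick <- px[sample.int(nrow(px), n_t, replace = TRUE), , drop = FALSE]
    tx_list[[j]] <- data.frame(
      x = fr$origin[1] + (pick[, 2] - 1L) * s + stats::runif(n_t, 0, s),
      y = fr$origin[2] + (pick[, 1] - 1L) * s + stats::runif(n_t, 0, s),
      gene = colnames(profiles)[sample.int(p$n_genes, n_t, replace = TRUE,
                                           prob = profiles[cell_types[j], ])],
      qv = 20 + stats::rgamma(n_t, shape = 2, scale = 7),
      cell = j)
  }
  n_bg <- stats::rpois(1, p$background_transcript_rate * wd * ht)
  if (n_bg > 0) {
    tx_list[[n_kept + 1L]] <- data.frame(
      x = stats::runif(n_bg, fr$origin[1], fr$origin[1] + wd),
      y = stats::runif(n_bg, fr$origin[2], fr$origin[2] + ht),
      gene = colnames(profiles)[sample.int(p$n_genes, n_bg, replace = TRUE)],
      qv = 40 * stats::rbeta(n_bg, 2, 5),
      cell = 0L)
  }
  tx <- do.call(rbind, tx_list[!vapply(tx_list, is.null, logical(1))])
  if (is.null(tx))
    tx <- data.frame(x = numeric(), y = numeric(), gene = character(),
                     qv = numeric(), cell = integer())
  rownames(tx) <- NULL
  transcripts <- as_transcript_table(tx)

  # --- DAPI ---
  bright <- stats::runif(n_kept, 0.65, 1)
  dapi_v <- matrix(0, H, W)
  nz <- nuc > 0L
  dapi_v[nz] <- bright[nuc[nz]]
  dapi_v <- from_ebi(EBImage::gblur(as_ebi(dapi_v), sigma = 1.5))
  if (p$dapi_noise_sd > 0)
    dapi_v <- dapi_v + stats::rnorm(H * W, 0, p$dapi_noise_sd)
  dapi <- intensity_image(pmax(dapi_v, 0), fr)

  polys <- lapply(seq_len(n_kept), function(j) polygon_from_mask(cell_mask, j))

  structure(list(cell_mask = cell_mask, nucleus_mask = nucleus_mask,
                 cell_polygons = polys, cell_types = cell_types,
                 transcripts = transcripts, dapi = dapi,
                 gene_profiles = profiles, params = p),
            class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf(
    "<synthetic_tissue> %s: %d cells, %d types, %d transcripts\n",
    format(x$cell_mask$frame), length(mask_labels(x$cell_mask)),
    length(unique(x$cell_types)), nrow(x$transcripts)))
  invisible(x)
}

#' Rasterize boundary polygons into a label mask
#'
#' A pixel gets the label of the polygon containing its centre; pixels in
#' no polygon stay background.  Polygon interiors must be pairwise
#' disjoint.
#'
#' @param polygons List of [cell_polygon()]s.
#' @param frame Target [pixel_frame()].
#' @return A [label_mask()].
#' @export
rasterize_polygons <- function(polygons, frame) {
  assert_frame(frame)
  H <- frame$height; W <- frame$width
  lab <- matrix(0L, H, W)
  grid <- pixel_center_grid(frame)
  clashes <- character(0)
  for (p in polygons) {
    stopifnot(inherits(p, "cell_polygon"))
    v <- p$vertices
    cols <- which(grid$x >= min(v[, 1]) & grid$x <= max(v[, 1]))
    rows <- which(grid$y >= min(v[, 2]) & grid$y <= max(v[, 2]))
    if (!length(rows) || !length(cols)) next
    pts <- cbind(rep(grid$x[cols], each = length(rows)),
                 rep(grid$y[rows], times = length(cols)))
    inside <- points_in_polygon(pts, v)
    if (!any(inside)) next
    idx <- cbind(rep(rows, times = length(cols)),
                 rep(cols, each = length(rows)))[inside, , drop = FALSE]
    prev <- lab[idx]
    if (any(prev != 0L))
      clashes <- c(clashes, paste(unique(prev[prev != 0L]), "vs", p$label))
    lab[idx] <- as.integer(p$label)
  }
  if (length(clashes))
    stop("overlapping polygon interiors: ", paste(clashes, collapse = "; "))
  label_mask(lab, frame)
}

#' Write a full synthetic tissue bundle to a directory
#'
#' Emits the cell and nucleus mask TIFFs, the DAPI TIFF, the boundary
#' polygons as GeoJSON, the transcripts as parquet and a JSON truth table
#' (cell types, gene profiles, parameters).
#'
#' @param tissue A `synthetic_tissue`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tissue <- function(tissue, dir) {
  stopifnot(inherits(tissue, "synthetic_tissue"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_label_mask(tissue$cell_mask, file.path(dir, "cell_mask.tif"))
  write_label_mask(tissue$nucleus_mask, file.path(dir, "nucleus_mask.tif"))
  write_intensity_image(tissue$dapi, file.path(dir, "dapi.tif"))
  write_polygons(tissue$cell_polygons, file.path(dir, "cell_polygons.geojson"))
  write_transcripts(tissue$transcripts, file.path(dir, "transcripts.parquet"))
  pars <- tissue$params
  pars$frame <- list(width = pars$frame$width, height = pars$frame$height,
                     pixel_size = pars$frame$pixel_size,
                     origin = pars$frame$origin)
  jsonlite::write_json(
    list(cell_types = as.list(tissue$cell_types),
         gene_profiles = tissue$gene_profiles,
         params = unclass(pars)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
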