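test_that("a single centred cell yields a contained centred nucleus", {
  p <- simulation_params(n_cells = 1, frame = pixel_frame(64, 64, 0.5),
                         nucleus_offset_fraction = 0,
                         cell_elongation_range = c(1, 1),
                         background_transcript_rate = 0,
                         dapi_noise_sd = 0, seed = 3)
  tis <- simulate_tissue(p)
  expect_length(mask_labels(tis$cell_mask), 1)
  expect_length(mask_labels(tis$nucleus_mask), 1)
  # nucleus strictly inside its cell
  nuc <- tis$nucleus_mask$labels
  expect_true(all(tis$cell_mask$labels[nuc > 0] == nuc[nuc > 0]))
  # nucleus smaller than the cell, near the requested fraction
  frac <- sum(nuc > 0) / sum(tis$cell_mask$labels > 0)
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.5)
  # offset 0: nucleus centroid close to cell centroid
  ci <- which(tis$cell_mask$labels == 1, arr.ind = TRUE)
  ni <- which(nuc == 1, arr.ind = TRUE)
  expect_lt(sqrt(sum((colMeans(ci) - colMeans(ni)) ^ 2)), 3)
  # all transcripts inside the cell mask
  a <- assign_transcripts(tis$cell_mask, tis$transcripts)
  expect_true(all(a == 1))
})

test_that("without background every transcript lies inside a cell", {
  tis <- small_tissue(seed = 21, background_transcript_rate = 0)
  a <- assign_transcripts(tis$cell_mask, filter_transcripts(tis$transcripts))
  expect_true(all(a > 0))
})

test_that("the same seed reproduces the tissue bit-for-bit", {
  p <- simulation_params(n_cells = 25, frame = pixel_frame(160, 160, 0.5),
                         seed = 5)
  t1 <- simulate_tissue(p)
  t2 <- simulate_tissue(p)
  expect_identical(t1$cell_mask$labels, t2$cell_mask$labels)
  expect_identical(t1$nucleus_mask$labels, t2$nucleus_mask$labels)
  expect_equal(as.data.frame(t1$transcripts), as.data.frame(t2$transcripts))
  expect_equal(t1$dapi$values, t2$dapi$values)
  # a different seed gives a different molecule count
  t3 <- simulate_tissue(simulation_params(n_cells = 25,
                                          frame = pixel_frame(160, 160, 0.5),
                                          seed = 6))
  expect_false(nrow(t3$transcripts) == nrow(t1$transcripts) &&
                 identical(t1$cell_mask$labels, t3$cell_mask$labels))
})

test_that("transcript-in-cell fraction decreases with background rate", {
  fracs <- vapply(c(0, 0.05, 0.3), function(rate) {
    tis <- small_tissue(seed = 31, background_transcript_rate = rate)
    mean(assign_transcripts(tis$cell_mask, tis$transcripts) > 0)
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
})

test_that("nucleus offset scales the nucleus-to-cell centroid distance", {
  centroid_d <- function(tis) {
    labs <- mask_labels(tis$cell_mask)
    vapply(labs, function(l) {
      ci <- which(tis$cell_mask$labels == l, arr.ind = TRUE)
      ni <- which(tis$nucleus_mask$labels == l, arr.ind = TRUE)
      sqrt(sum((colMeans(ci) - colMeans(ni)) ^ 2))
    }, numeric(1))
  }
  lo <- centroid_d(small_tissue(seed = 41, nucleus_offset_fraction = 0.05))
  hi <- centroid_d(small_tissue(seed = 41, nucleus_offset_fraction = 0.45))
  expect_gt(mean(hi), mean(lo))
  # rank correlation across the offset sweep
  offs <- c(0.05, 0.15, 0.25, 0.35, 0.45)
  means <- vapply(offs, function(o)
    mean(centroid_d(small_tissue(seed = 41, nucleus_offset_fraction = o))),
    numeric(1))
  expect_gt(cor(offs, means, method = "spearman"), 0.8)
})

test_that("mask lookup and polygon containment agree on transcript placement", {
  tis <- small_tissue(seed = 51)
  tx <- filter_transcripts(tis$transcripts)
  by_mask <- mean(assign_transcripts(tis$cell_mask, tx) > 0)
  pts <- cbind(tx$x, tx$y)
  in_poly <- rep(FALSE, nrow(pts))
  for (p in tis$cell_polygons) {
    v <- p$vertices
    box <- pts[, 1] >= min(v[, 1]) & pts[, 1] <= max(v[, 1]) &
      pts[, 2] >= min(v[, 2]) & pts[, 2] <= max(v[, 2])
    if (any(box))
      in_poly[box] <- in_poly[box] |
        txseg:::points_in_polygon(pts[box, , drop = FALSE], v)
  }
  expect_lt(abs(by_mask - mean(in_poly)), 0.01)
})

test_that("an overfull frame raises a packing error", {
  expect_error(
    simulate_tissue(simulation_params(n_cells = 500,
                                      frame = pixel_frame(64, 64, 0.5),
                                      seed = 1)),
    "packing")
})

test_that("rasterize_polygons uses pixel-centre containment", {
  fr <- pixel_frame(6, 6, 1)
  # an axis-aligned 2x2-pixel square covering pixel centres (2:3, 2:3)
  sq <- cell_polygon(rbind(c(1, 1), c(3, 1), c(3, 3), c(1, 3)), 4)
  m <- rasterize_polygons(list(sq), fr)
  expect_equal(sum(m$labels == 4L), 4)
  expect_equal(which(m$labels == 4L, arr.ind = TRUE),
               cbind(row = c(2L, 3L, 2L, 3L), col = c(2L, 2L, 3L, 3L)),
               ignore_attr = TRUE)

  # empty list -> all-zero mask
  expect_length(mask_labels(rasterize_polygons(list(), fr)), 0)

  # overlapping interiors are an error naming the labels
  sq2 <- cell_polygon(rbind(c(2, 2), c(4, 2), c(4, 4), c(2, 4)), 9)
  expect_error(rasterize_polygons(list(sq, sq2), fr), "overlap")
})

test_that("rasterized area approximates polygon area within a perimeter band", {
  set.seed(6)
  fr <- pixel_frame(120, 120, 0.5)
  for (i in 1:10) {
    v <- random_convex_polygon(15, scale = 8)
    v <- sweep(v, 2, c(30, 30), "+")
    p <- cell_polygon(v, 1)
    m <- rasterize_polygons(list(p), fr)
    a_pix <- sum(m$labels > 0) * 0.25
    a_poly <- polygon_area(p)
    expect_lt(abs(a_pix - a_poly), polygon_perimeter(p) * 0.5 + 0.25)
  }
})

test_that("a tissue bundle writes and reads back consistently", {
  d <- withr::local_tempdir()
  tis <- small_tissue(seed = 61)
  write_tissue(tis, d)
  cm <- read_label_mask(file.path(d, "cell_mask.tif"))
  expect_identical(cm$labels, tis$cell_mask$labels)
  tx <- read_transcripts(file.path(d, "transcripts.parquet"))
  expect_equal(nrow(tx), nrow(tis$transcripts))
  polys <- read_polygons(file.path(d, "cell_polygons.geojson"))
  expect_length(polys, length(tis$cell_polygons))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(length(truth$cell_types), length(tis$cell_types))
})
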