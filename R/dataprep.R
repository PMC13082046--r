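#' Quality-filter a transcript table
#'
#' Keeps exactly the molecules with `qv >= qv_min` (threshold inclusive),
#' preserving row order.  Idempotent.
#'
#' @param transcripts A [transcript_table()].
#' @param qv_min Quality threshold (default 20).
#' @return The filtered [transcript_table()].
#' @export
filter_transcripts <- function(transcripts, qv_min = 20) {
  validate_transcripts(transcripts)
  out <- transcripts[transcripts$qv >= qv_min, , drop = FALSE]
  rownames(out) <- NULL
  as_transcript_table(out)
}

#' Sample qualifying image tiles from a cell mask
#'
#' Candidate windows lie on a stride grid (default stride `tile_size / 2`)
#' and are visited in uniformly random order without replacement.  A window
#' qualifies iff it contains at least `min_cell_pixels` non-background
#' pixels and intersects at least `min_cells` distinct instances (any
#' overlap counts; cells need not be fully contained).  Sampling stops once
#' `n_tiles` qualifying windows are found or all candidates are exhausted,
#' in which case the (shorter) result carries attribute `exhausted = TRUE`.
#'
#' @param cell_mask A [label_mask()] of whole-cell instances.
#' @param tile_size Tile edge length in pixels (default 256).
#' @param n_tiles Number of tiles requested.
#' @param min_cell_pixels Minimum non-background pixels per tile
#'   (default 200).
#' @param min_cells Minimum distinct instances intersecting the tile
#'   (default 15).
#' @param seed Integer seed controlling the sampling order.
#' @param stride Candidate grid stride in pixels.
#' @return A list of `tile` objects: `id`, `window` (`c(row, col, nrow,
#'   ncol)`), `split` (`"unassigned"`), `stats` (`cell_pixels`, `n_cells`).
#' @export
select_tiles <- function(cell_mask, tile_size = 256, n_tiles = 1000,
                         min_cell_pixels = 200, min_cells = 15,
                         seed = 1L, stride = max(1L, tile_size %/% 2L)) {
  stopifnot(inherits(cell_mask, "label_mask"))
  H <- cell_mask$frame$height; W <- cell_mask$frame$width
  tile_size <- as.integer(tile_size)
  if (tile_size > H || tile_size > W)
    stop("tile_size exceeds the frame dimensions")
  r0 <- unique(c(seq(1L, H - tile_size + 1L, by = stride), H - tile_size + 1L))
  c0 <- unique(c(seq(1L, W - tile_size + 1L, by = stride), W - tile_size + 1L))
  cand <- expand.grid(row = r0, col = c0)
  ord <- with_seed(seed, sample.int(nrow(cand)))
  tiles <- list()
  for (i in ord) {
    if (length(tiles) >= n_tiles) break
    rows <- seq.int(cand$row[i], length.out = tile_size)
    cols <- seq.int(cand$col[i], length.out = tile_size)
    sub <- cell_mask$labels[rows, cols]
    npix <- sum(sub > 0L)
    if (npix < min_cell_pixels) next
    ncell <- length(unique(sub[sub > 0L]))
    if (ncell < min_cells) next
    tiles[[length(tiles) + 1L]] <- structure(
      list(id = sprintf("tile_%04d", length(tiles) + 1L),
           window = c(cand$row[i], cand$col[i], tile_size, tile_size),
           split = "unassigned",
           stats = list(cell_pixels = npix, n_cells = ncell)),
      class = "tile")
  }
  if (length(tiles) < n_tiles) {
    warning(sprintf("only %d of %d requested tiles qualify",
                    length(tiles), n_tiles))
    attr(tiles, "exhausted") <- TRUE
  }
  tiles
}

#' Randomly split tiles into training and test sets
#'
#' A uniform random partition without overlap; tiles beyond
#' `n_train + n_test` stay `"unassigned"`.  Deterministic per seed.
#'
#' @param tiles List of tiles from [select_tiles()].
#' @param n_train,n_test Split sizes; their sum must not exceed the number
#'   of tiles.
#' @param seed Integer seed.
#' @return The tile list with `split` set to `"train"` / `"test"` /
#'   `"unassigned"`.
#' @export
split_tiles <- function(tiles, n_train = 800, n_test = 200, seed = 1L) {
  n <- length(tiles)
  if (n_train + n_test > n)
    stop(sprintf("cannot split %d tiles into %d train + %d test",
                 n, n_train, n_test))
  picked <- with_seed(seed, sample.int(n, n_train + n_test))
  for (i in seq_len(n)) tiles[[i]]$split <- "unassigned"
  for (i in picked[seq_len(n_train)]) tiles[[i]]$split <- "train"
  if (n_test > 0)
    for (i in picked[n_train + seq_len(n_test)]) tiles[[i]]$split <- "test"
  tiles
}

#' Export model-ready training pairs
#'
#' Writes, for every tile, the two-channel input stack and the
#' corresponding ground-truth mask as TIFFs, plus a JSON manifest recording
#' windows, splits, per-tile stats and the reference training
#' hyperparameters (300 epochs, learning rate 1e-3, weight decay 1e-5) so
#' an external trainer can reproduce the protocol.  Training itself is out
#' of scope for this package (it needs GPU-scale resources); the export is
#' the backend contract.
#'
#' @param tiles Tiles from [split_tiles()].
#' @param stack A full-frame [channel_stack()].
#' @param cell_mask The full-frame ground-truth [label_mask()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
export_training <- function(tiles, stack, cell_mask, dir) {
  stopifnot(inherits(stack, "channel_stack"),
            inherits(cell_mask, "label_mask"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(tiles, function(tl) {
    img_path <- file.path(dir, paste0(tl$id, "_img.tif"))
    msk_path <- file.path(dir, paste0(tl$id, "_mask.tif"))
    sub <- channel_stack(crop(stack$dapi, tl$window),
                         crop(stack$density, tl$window))
    write_channel_stack(sub, img_path)
    write_label_mask(crop(cell_mask, tl$window), msk_path)
    list(id = tl$id, window = tl$window, split = tl$split,
         stats = tl$stats, image = basename(img_path),
         mask = basename(msk_path))
  })
  manifest <- list(
    tiles = entries,
    training = list(epochs = 300, learning_rate = 1e-3,
                    weight_decay = 1e-5,
                    architecture = "two-channel instance segmentation"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
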