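# Small shared tissue fixtures, built once per test run and memoised.

small_tissue_cache <- new.env(parent = emptyenv())

small_tissue <- function(seed = 11, ...) {
  extra <- list(...)
  key <- paste0("t", seed, "_",
                paste(names(extra), vapply(extra, format, character(1)),
                      sep = "=", collapse = ";"))
  if (!is.null(small_tissue_cache[[key]])) return(small_tissue_cache[[key]])
  params <- simulation_params(
    n_cells = 40,
    frame = pixel_frame(224, 224, 0.5),
    transcripts_per_cell_mean = 60,
    seed = seed, ...)
  tis <- simulate_tissue(params)
  small_tissue_cache[[key]] <- tis
  tis
}
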