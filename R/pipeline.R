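#' Default run configuration
#'
#' Collects every stage parameter in one declarative list: pixel size,
#' density sigma, quality threshold, tile size and qualification
#' thresholds, split sizes, expansion distance, clustering target and
#' classifier settings.  `run_pipeline()` validates the configuration
#' against each stage's preconditions as it goes.
#'
#' @param seed Master seed; stage seeds derive from it.
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    pixel_size = 0.5,
    frame_px = 384,
    n_cells = 120,
    sigma = 2.5,
    qv_min = 20,
    tile_size = 128,
    n_tiles = 8,
    min_cell_pixels = 200,
    min_cells = 15,
    n_train = 6,
    n_test = 2,
    expansion_um = 5,
    align_threshold = 0.3,
    # the simulator's default tissue has 5 types; cluster toward that
    target_k = 5,
    top_k_classes = 5,
    test_fraction = 0.2,
    n_trees = 500,
    segmenter = "expansion",
    output_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Read a run configuration from YAML
#'
#' Unknown keys raise a validation error naming the key; missing keys take
#' the defaults.
#'
#' @param path YAML file of key-value overrides.
#' @return A config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  over <- yaml::read_yaml(path)
  do.call(default_config, c(list(seed = over$seed %||% 1L),
                            over[setdiff(names(over), "seed")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-tissue workflow
#'
#' Executes simulate -> pseudoimage -> segment (nuclear expansion and/or
#' fallback) -> IoU evaluation -> alignment -> clustering agreement ->
#' morphology -> classification on one synthetic tissue, and returns (and
#' optionally writes) a structured report.  All randomness flows from
#' `config$seed`; rerunning with the same config reproduces the report.
#'
#' @param config A list from [default_config()] / [read_config()].
#' @return A `pipeline_report` list; written as JSON to
#'   `config$output_dir` when set.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- do.call(default_config, config[names(config) != ""])
  fr <- pixel_frame(cfg$frame_px, cfg$frame_px, cfg$pixel_size)
  tissue <- simulate_tissue(simulation_params(
    n_cells = cfg$n_cells, frame = fr, seed = cfg$seed))
  stack <- build_stack(tissue$dapi, tissue$transcripts, fr,
                       density_params(sigma = cfg$sigma,
                                      qv_min = cfg$qv_min))
  pred <- switch(cfg$segmenter,
                 expansion = expand_nuclei(tissue$nucleus_mask,
                                           cfg$expansion_um),
                 fallback = segment_fallback(stack, tissue$nucleus_mask),
                 stop("unknown segmenter: ", cfg$segmenter))

  tx_qc <- filter_transcripts(tissue$transcripts, cfg$qv_min)
  m <- iou_matrix(tissue$cell_mask, pred)
  img <- image_iou(m)
  ga <- assign_transcripts(tissue$cell_mask, tx_qc)
  pa <- assign_transcripts(pred, tx_qc)
  gen <- gene_iou(ga, pa, pred_labels = mask_labels(pred))
  aligned <- align_cells(m, cfg$align_threshold)

  report <- list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    n_cells_truth = length(mask_labels(tissue$cell_mask)),
    n_cells_pred = length(mask_labels(pred)),
    image_iou = img$tile_mean,
    gene_iou = gen$tile_mean,
    n_aligned = nrow(aligned))

  # clustering agreement on aligned cells (predicted counts vs truth types)
  if (nrow(aligned) >= cfg$target_k) {
    cm <- count_matrix(pa, tx_qc, aligned$pred)
    lab <- tryCatch(
      cluster_cells(cm, target_k = cfg$target_k, seed = cfg$seed),
      error = function(e) NULL)
    if (!is.null(lab)) {
      truth_types <- tissue$cell_types[as.character(aligned$gt)]
      agr <- agreement(truth_types, lab)
      report$clustering <- list(k = attr(lab, "k"),
                                ari = agr$ari, ami = agr$ami,
                                homogeneity = agr$homogeneity,
                                completeness = agr$completeness)
    }
  }

  # morphology on truth vs prediction
  feat_gt <- features_from_mask(tissue$cell_mask)
  feat_pred <- features_from_mask(pred)
  report$morphology <- list(
    truth = colMeans(feat_gt[-1]),
    predicted = colMeans(feat_pred[-1]))

  types_gt <- tissue$cell_types[as.character(feat_gt$label)]
  rf <- tryCatch(
    rf_evaluate(feat_gt[-1], paste0("type", types_gt),
                top_k = cfg$top_k_classes,
                test_fraction = cfg$test_fraction,
                n_trees = cfg$n_trees, seed = cfg$seed),
    error = function(e) NULL)
  if (!is.null(rf))
    report$classification <- list(accuracy = rf$accuracy,
                                  macro_f1 = rf$macro_f1,
                                  macro_auc = rf$macro_auc)

  class(report) <- "pipeline_report"
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d truth / %d predicted cells\n",
              x$n_cells_truth, x$n_cells_pred))
  cat(sprintf("  image IoU %.4f | gene IoU %.4f | aligned %d\n",
              x$image_iou, x$gene_iou, x$n_aligned))
  if (!is.null(x$clustering))
    cat(sprintf("  clustering k = %d, ARI %.3f, AMI %.3f\n",
                x$clustering$k, x$clustering$ari, x$clustering$ami))
  if (!is.null(x$classification))
    cat(sprintf("  morphology RF: acc %.3f, macro-F1 %.3f, macro-AUC %.3f\n",
                x$classification$accuracy, x$classification$macro_f1,
                x$classification$macro_auc))
  invisible(x)
}
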