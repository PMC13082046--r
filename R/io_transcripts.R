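#' Read and write per-molecule transcript tables
#'
#' Three dialects are supported:
#' * `"xenium-csv"` — the Xenium `transcripts.csv` layout; columns
#'   `x_location`, `y_location`, `feature_name`, `qv` are mapped to
#'   `x`, `y`, `gene`, `qv`.
#' * `"generic-csv"` — any CSV already carrying `x`, `y`, `gene`, `qv`.
#' * `"parquet"` — a parquet file with `x`, `y`, `gene`, `qv` columns.
#'
#' With `dialect = "auto"` (default) parquet is picked by file extension and
#' the CSV dialect by header inspection.  No quality filtering is applied at
#' read time; see [filter_transcripts()].
#'
#' @param path File path.
#' @param dialect One of `"auto"`, `"xenium-csv"`, `"generic-csv"`,
#'   `"parquet"`.
#' @return A [transcript_table()]; extra columns are carried through.
#' @export
read_transcripts <- function(path, dialect = c("auto", "xenium-csv",
                                               "generic-csv", "parquet")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read transcripts: no such file: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.parquet$", path, ignore.case = TRUE))
      "parquet" else "csv-sniff"
  df <- if (dialect == "parquet") {
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (dialect == "csv-sniff")
    dialect <- if ("x_location" %in% names(df)) "xenium-csv" else "generic-csv"
  if (dialect == "xenium-csv") {
    map <- c(x = "x_location", y = "y_location", gene = "feature_name",
             qv = "qv")
    miss <- setdiff(unname(map), names(df))
    if (length(miss))
      stop("xenium-csv file is missing required column(s): ",
           paste(miss, collapse = ", "))
    keep <- setdiff(names(df), unname(map))
    out <- df[unname(map)]
    names(out) <- names(map)
    df <- cbind(out, df[keep])
  } else {
    miss <- setdiff(c("x", "y", "gene", "qv"), names(df))
    if (length(miss))
      stop(dialect, " file is missing required column(s): ",
           paste(miss, collapse = ", "))
  }
  df$gene <- as.character(df$gene)
  rownames(df) <- NULL
  as_transcript_table(df)
}

#' @rdname read_transcripts
#' @param transcripts A [transcript_table()].
#' @param format `"parquet"` or `"csv"` (generic dialect).
#' @export
write_transcripts <- function(transcripts, path,
                              format = c("parquet", "csv")) {
  format <- match.arg(format)
  validate_transcripts(transcripts)
  df <- as.data.frame(transcripts)
  if (format == "parquet") {
    arrow::write_parquet(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
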