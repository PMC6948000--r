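# TSV/JSON readers and writers. Numeric columns are serialized with 17
# significant digits so every writer/reader pair round-trips losslessly.

.format_numeric <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write / read a probes-by-samples matrix as TSV
#'
#' Layout: header row of sample IDs, first column `probe_id`, one row per
#' probe. Used for methylation beta matrices and detection p-value matrices
#' alike.
#'
#' @param mat numeric matrix with dimnames.
#' @param path file path.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat),
                   matrix(sprintf("%.17g", mat), nrow(mat),
                          dimnames = list(NULL, colnames(mat))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "probe_id"))
  mat <- as.matrix(dt[, -1, with = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- dt$probe_id
  mat
}

#' Write / read a data.frame as TSV (lossless numerics)
#'
#' @param df data.frame (phenotype table, truth table, summary table,
#'   comparison records, annotation tables).
#' @param path file path.
#' @return `write_table_tsv` returns `path` invisibly; `read_table_tsv`
#'   returns a data.frame.
#' @export
write_table_tsv <- function(df, path) {
  data.table::fwrite(.format_numeric(as.data.frame(df)), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

#' Read a summary table TSV into an `ewas_summary`
#'
#' Expects the bit-stable column order written by the package:
#' probe_id, trait, cohort, ancestry, n, effect, se, p, ci_low, ci_high,
#' model_id. This is also the ingestion format for external reference-study
#' statistics.
#'
#' @param path file path.
#' @param level confidence level the `ci_*` columns were computed at.
#' @return an `ewas_summary` data.frame.
#' @export
read_summary_tsv <- function(path, level = 0.95) {
  df <- read_table_tsv(path)
  need <- c("probe_id", "trait", "cohort", "ancestry", "n", "effect", "se",
            "p", "ci_low", "ci_high", "model_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("summary TSV missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[, need]
  attr(df, "level") <- level
  class(df) <- c("ewas_summary", "data.frame")
  df
}

#' Write a run configuration or report as JSON
#'
#' @param x a list.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_json_file
#' @export
read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
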