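# Plain-text tabular I/O. Matrices travel as CSV/TSV, either wide
# (samples x features, first column "sample_id") or long
# ("sample_id", "feature_id", "value"); the layout is auto-detected from
# the header. Reports are written as TSV plus a JSON summary.

sep_for <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Read a concentration matrix from CSV/TSV
#'
#' Wide layout (first column `sample_id`, remaining columns features) and
#' long layout (`sample_id`, `feature_id`, `value`) are auto-detected from
#' the header. Empty cells become `NA` (missing).
#'
#' @param path CSV or TSV file path.
#' @return Samples x features numeric matrix.
#' @export
read_concentration_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("sample_id", "feature_id", "value") %in% names(df))) {
    samples <- unique(df$sample_id)
    features <- unique(df$feature_id)
    m <- matrix(NA_real_, length(samples), length(features),
                dimnames = list(samples, features))
    m[cbind(match(df$sample_id, samples), match(df$feature_id, features))] <-
      df$value
    return(m)
  }
  if (names(df)[1] != "sample_id")
    stopf("read_concentration_matrix: expected 'sample_id' first column or long layout in %s",
          path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

#' Write a concentration matrix as CSV/TSV (wide layout)
#'
#' @param matrix Samples x features matrix.
#' @param path Output file; `.tsv` extension selects tab separation.
#' @export
write_concentration_matrix <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep_for(path), row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read / write sample manifests, annotations and covariate tables
#'
#' Thin CSV/TSV wrappers; `read_manifest` validates required columns and
#' fills a missing `exclusion` column with `"none"`.
#'
#' @param path CSV or TSV file path.
#' @return A data frame.
#' @export
read_manifest <- function(path) {
  check_manifest(utils::read.table(path, header = TRUE, sep = sep_for(path),
                                   stringsAsFactors = FALSE))
}

#' @rdname read_manifest
#' @param table Data frame to write.
#' @export
write_table_file <- function(table, path) {
  utils::write.table(table, path, sep = sep_for(path), row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Write an outlier report as TSV + JSON
#'
#' @param report An `outlier_report`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` (per-sample
#'   scores and flags) and `<prefix>.json` (thresholds and declared set).
#' @export
write_outlier_report <- function(report, prefix) {
  tab <- data.frame(sample_id = names(report$sum_abs_z),
                    sum_abs_z = report$sum_abs_z,
                    pc_distance = report$pc_distance,
                    flagged_zsum = names(report$sum_abs_z) %in% report$flagged_zsum,
                    flagged_pc = names(report$sum_abs_z) %in% report$flagged_pc,
                    declared = names(report$sum_abs_z) %in% report$declared,
                    stringsAsFactors = FALSE)
  write_table_file(tab, paste0(prefix, ".tsv"))
  jsonlite::write_json(list(threshold_zsum = report$threshold_zsum,
                            threshold_pc = report$threshold_pc,
                            n_components = report$n_components,
                            percentile = report$percentile,
                            declared = report$declared),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' @param path `.yaml`/`.yml` or `.json` configuration file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
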