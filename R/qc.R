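# Analytical quality metrics from pooled QC replicates.

#' Coefficient of variation from QC replicates
#'
#' Per feature, CV = 100 x sample SD / mean over the replicate samples of
#' the given role, on the concentration scale (the field convention behind
#' the usual 20% acceptance threshold). Summaries are the median CV and the
#' fraction of features with CV below 20%.
#'
#' @param matrix Samples x features concentration matrix.
#' @param manifest Sample manifest.
#' @param role QC role to evaluate (default `"PQC"`); needs at least 2
#'   samples.
#' @param features Optional feature ids to restrict to (e.g. retained
#'   measures).
#' @return An object of class `cv_report`: per-feature `cv` (percent),
#'   `median_cv`, `frac_below_20`, `n_samples`, `role`.
#' @examples
#' m <- matrix(c(9, 10, 11), 3, 1,
#'             dimnames = list(paste0("q", 1:3), "F1"))
#' mf <- data.frame(sample_id = paste0("q", 1:3), role = "PQC", batch = "B1")
#' compute_cv(m, mf)$cv   # 10
#' @export
compute_cv <- function(matrix, manifest, role = "PQC", features = NULL) {
  check_matrix(matrix)
  manifest <- check_manifest(manifest, rownames(matrix))
  ids <- manifest$sample_id[manifest$role == role]
  if (length(ids) < 2L)
    stopf("compute_cv: need at least 2 samples with role '%s'", role)
  X <- matrix[rownames(matrix) %in% ids, , drop = FALSE]
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  cv <- 100 * apply(X, 2L, stats::sd, na.rm = TRUE) /
    colMeans(X, na.rm = TRUE)
  structure(list(cv = cv,
                 median_cv = stats::median(cv, na.rm = TRUE),
                 frac_below_20 = mean(cv < 20, na.rm = TRUE),
                 n_samples = nrow(X), role = role),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("CV report (%s, %d replicates): median CV %.1f%%, %.1f%% of features < 20%%\n",
              x$role, x$n_samples, x$median_cv, 100 * x$frac_below_20))
  invisible(x)
}
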