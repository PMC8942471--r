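# Preprocessing chain, in its fixed order:
# zero replacement -> batch harmonization -> kNN imputation -> dual-criterion
# outlier detection -> exclusions; plus feature retention and class totals.
# All log transforms are base 10.

#' Replace below-detection zeros
#'
#' Within each sample-type group (timepoint x matrix for biological samples;
#' each QC role its own group), every zero for a feature is replaced by one
#' tenth of the minimum positive observed value of that feature in the
#' group. Positive and missing entries are unchanged. A feature with no
#' positive value in a group has its zeros set to missing, with a warning
#' (no positive minimum exists to divide).
#'
#' @param matrix Samples x features concentration matrix (`NA` = missing).
#' @param manifest Sample manifest.
#' @return Matrix with zeros replaced.
#' @examples
#' m <- matrix(c(0, 2, 10), 3, 1,
#'             dimnames = list(paste0("s", 1:3), "F1"))
#' mf <- data.frame(sample_id = paste0("s", 1:3), role = "biological",
#'                  batch = "B1", timepoint = "6m", matrix = "plasma")
#' replace_zeros(m, mf)[, 1]   # 0.2 2 10
#' @export
replace_zeros <- function(matrix, manifest) {
  check_matrix(matrix)
  manifest <- check_manifest(manifest, rownames(matrix))
  grp <- sample_type_groups(manifest)[rownames(matrix)]
  degenerate <- character(0)
  for (g in unique(grp)) {
    rows <- which(grp == g)
    for (j in seq_len(ncol(matrix))) {
      v <- matrix[rows, j]
      z <- which(!is.na(v) & v == 0)
      if (!length(z)) next
      pos <- v[!is.na(v) & v > 0]
      if (length(pos)) {
        matrix[rows[z], j] <- min(pos) / 10
      } else {
        matrix[rows[z], j] <- NA_real_
        degenerate <- c(degenerate, sprintf("%s in group %s", colnames(matrix)[j], g))
      }
    }
  }
  if (length(degenerate))
    warning(sprintf(
      "replace_zeros: no positive minimum for %d feature-group(s); zeros set to missing (%s%s)",
      length(degenerate), paste(utils::head(degenerate, 3L), collapse = "; "),
      if (length(degenerate) > 3L) "; ..." else ""), call. = FALSE)
  matrix
}

#' Harmonize concentrations across analytical batches
#'
#' Aligns batches on the log10 scale, per feature: (1) every sample of
#' batch `b` is shifted by (global PQC median - batch-`b` PQC median), so
#' pooled-QC medians agree across batches; (2) each batch is rescaled about
#' its biological-sample median so that the batch-wise standard deviation
#' of biological samples equals the across-batch mean of those standard
#' deviations. QC samples receive the same affine correction as the
#' biological samples they anchor. Values are returned on the concentration
#' scale; within-batch rank order per feature is preserved.
#'
#' @param matrix Samples x features concentration matrix; zeros must have
#'   been replaced ([replace_zeros()]). Missing values are tolerated and
#'   ignored in the batch statistics.
#' @param manifest Sample manifest; every batch needs at least 2 PQC and
#'   2 biological samples.
#' @param sd_weighting `"unweighted"` (default) averages batch SDs equally;
#'   `"weighted"` weights by biological sample count.
#' @return Harmonized concentration matrix.
#' @export
harmonize_batches <- function(matrix, manifest,
                              sd_weighting = c("unweighted", "weighted")) {
  sd_weighting <- match.arg(sd_weighting)
  check_matrix(matrix)
  manifest <- check_manifest(manifest, rownames(matrix))
  manifest <- manifest[match(rownames(matrix), manifest$sample_id), ]
  batches <- unique(manifest$batch)
  for (b in batches) {
    if (sum(manifest$batch == b & manifest$role == "PQC") < 2L)
      stopf("harmonize_batches: batch '%s' has fewer than 2 PQC samples", b)
    if (sum(manifest$batch == b & manifest$role == "biological") < 2L)
      stopf("harmonize_batches: batch '%s' has fewer than 2 biological samples", b)
  }
  L <- safe_log10(matrix, "harmonize_batches")
  pqc <- manifest$role == "PQC"
  bio <- manifest$role == "biological"

  # (1) PQC median centring
  g <- apply(L[pqc, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  for (b in batches) {
    rows <- manifest$batch == b
    d <- apply(L[rows & pqc, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    L[rows, ] <- sweep(L[rows, , drop = FALSE], 2L, g - d, `+`)
  }

  # (2) rescale batch-wise biological SDs to their across-batch mean
  sds <- t(vapply(batches, function(b)
    apply(L[manifest$batch == b & bio, , drop = FALSE], 2L, stats::sd,
          na.rm = TRUE), numeric(ncol(L))))
  w <- if (sd_weighting == "weighted")
    vapply(batches, function(b) sum(manifest$batch == b & bio), numeric(1))
  else rep(1, length(batches))
  target <- apply(sds, 2L, stats::weighted.mean, w = w, na.rm = TRUE)
  for (bi in seq_along(batches)) {
    rows <- manifest$batch == batches[bi]
    ctr <- apply(L[rows & bio, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    ratio <- target / sds[bi, ]
    ratio[!is.finite(ratio) | sds[bi, ] == 0] <- 1  # degenerate: leave unscaled
    sub <- sweep(L[rows, , drop = FALSE], 2L, ctr)
    sub <- sweep(sub, 2L, ratio, `*`)
    L[rows, ] <- sweep(sub, 2L, ctr, `+`)
  }
  out <- 10^L
  out[is.na(matrix)] <- NA_real_
  out
}

#' Impute missing values by k nearest neighbours in sample space
#'
#' Each missing entry `(s, f)` is replaced by the back-transformed mean
#' log10 value of feature `f` over the `k` samples nearest to `s` within
#' the same sample-type group. Distance is Euclidean over the log10 values
#' of features observed in both samples; only samples with feature `f`
#' observed are eligible neighbours (if fewer than `k` exist, all are
#' used). Observed values are never altered. Ties in distance are broken by
#' sample id lexicographic order.
#'
#' @param matrix Samples x features concentration matrix, zeros replaced.
#' @param manifest Sample manifest.
#' @param k Number of neighbours (default 5).
#' @return Complete concentration matrix.
#' @export
impute_knn <- function(matrix, manifest, k = 5L) {
  check_matrix(matrix)
  if (k < 1L) stopf("impute_knn: k must be >= 1")
  manifest <- check_manifest(manifest, rownames(matrix))
  if (!anyNA(matrix)) return(matrix)
  grp <- sample_type_groups(manifest)[rownames(matrix)]
  L <- safe_log10(matrix, "impute_knn")
  out <- L
  for (g in unique(grp)) {
    rows <- which(grp == g)
    if (!anyNA(L[rows, , drop = FALSE])) next
    if (length(rows) < k + 1L)
      stopf("impute_knn: group '%s' has %d samples; need at least k+1 = %d",
            g, length(rows), k + 1L)
    G <- L[rows, , drop = FALSE]
    all_missing <- colnames(G)[colSums(!is.na(G)) == 0L & colSums(is.na(G)) > 0L]
    if (length(all_missing))
      stopf("impute_knn: feature(s) missing in every sample of group '%s': %s",
            g, paste(all_missing, collapse = ", "))
    ids <- rownames(G)
    ord_ids <- order(ids)                       # lexicographic tie-break
    obs <- !is.na(G)
    need <- which(rowSums(!obs) > 0L)
    for (i in need) {
      d <- rep(Inf, nrow(G))
      for (t in seq_len(nrow(G))) {
        if (t == i) next
        joint <- obs[i, ] & obs[t, ]
        if (any(joint))
          d[t] <- sqrt(sum((G[i, joint] - G[t, joint])^2))
      }
      for (j in which(!obs[i, ])) {
        cand <- which(obs[, j] & is.finite(d))
        if (!length(cand))
          stopf("impute_knn: no usable neighbour for sample '%s', feature '%s'",
                ids[i], colnames(G)[j])
        cand <- cand[order(d[cand], match(cand, ord_ids))]
        nn <- utils::head(cand, k)
        out[rows[i], j] <- mean(G[nn, j])
      }
    }
  }
  res <- 10^out
  res[!is.na(matrix)] <- matrix[!is.na(matrix)]  # observed entries untouched
  res
}

#' Dual-criterion sample outlier detection
#'
#' Biological samples are scored two ways on the log10 scale: (A) per-feature
#' Z-scores are computed and their absolute values summed per sample;
#' samples above the 95th percentile of the sums are flagged. (B) the
#' Z-score matrix enters a principal components analysis (no second
#' centring or scaling); each sample's Euclidean distance to the origin in
#' the space of the first `n_components` component scores is computed, and
#' samples above the 95th percentile of distances are flagged. Samples
#' flagged by both criteria are declared outliers. Percentiles use linear
#' interpolation between order statistics and flagging is strict (`>`).
#'
#' @param matrix Complete (imputed) concentration matrix.
#' @param manifest Sample manifest; only biological samples are scored.
#' @param n_components Number of principal components retained (default 7).
#' @param percentile Flagging percentile as a fraction (default 0.95).
#' @return An object of class `outlier_report`: per-sample summed absolute
#'   Z-scores and PC distances, both thresholds, flag sets `flagged_zsum`
#'   and `flagged_pc`, `declared` (their intersection), `n_components`,
#'   `percentile`.
#' @export
detect_outliers <- function(matrix, manifest, n_components = 7L,
                            percentile = 0.95) {
  check_matrix(matrix)
  manifest <- check_manifest(manifest, rownames(matrix))
  bio_ids <- manifest$sample_id[manifest$role == "biological"]
  X <- matrix[rownames(matrix) %in% bio_ids, , drop = FALSE]
  if (nrow(X) < n_components + 1L)
    stopf("detect_outliers: need more than n_components = %d biological samples",
          n_components)
  if (anyNA(X))
    stopf("detect_outliers: matrix contains missing values; impute first")
  L <- safe_log10(X, "detect_outliers")
  mu <- colMeans(L)
  sdv <- apply(L, 2L, stats::sd)
  Z <- sweep(sweep(L, 2L, mu), 2L, ifelse(sdv > 0, sdv, 1), `/`)
  Z[, sdv == 0] <- 0

  zsum <- rowSums(abs(Z))
  thr_a <- unname(stats::quantile(zsum, percentile, type = 7))
  flagged_a <- sort(names(zsum)[zsum > thr_a])

  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$x))
  dist <- sqrt(rowSums(pc$x[, seq_len(nc), drop = FALSE]^2))
  thr_b <- unname(stats::quantile(dist, percentile, type = 7))
  flagged_b <- sort(names(dist)[dist > thr_b])

  structure(list(sum_abs_z = zsum, pc_distance = dist,
                 threshold_zsum = thr_a, threshold_pc = thr_b,
                 flagged_zsum = flagged_a, flagged_pc = flagged_b,
                 declared = intersect(flagged_a, flagged_b),
                 n_components = nc, percentile = percentile),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "Outlier report: %d samples scored; %d flagged by |Z|-sum, %d by %d-PC distance, %d declared (intersection)\n",
    length(x$sum_abs_z), length(x$flagged_zsum), length(x$flagged_pc),
    x$n_components, length(x$declared)))
  if (length(x$declared)) cat("declared:", paste(x$declared, collapse = ", "), "\n")
  invisible(x)
}

#' Apply sample exclusions
#'
#' Flags declared outliers in the manifest (pre-set `missed_injection` and
#' `maternal_contamination` flags take precedence and are kept) and
#' tabulates retention: retained = total - |missed U contaminated U
#' outliers|.
#'
#' @param manifest Sample manifest with an `exclusion` column.
#' @param report An `outlier_report` from [detect_outliers()], or a
#'   character vector of declared outlier ids.
#' @return List with `manifest` (updated) and `summary` (data frame of
#'   exclusion counts plus total and retained).
#' @export
apply_exclusions <- function(manifest, report) {
  manifest <- check_manifest(manifest)
  declared <- if (inherits(report, "outlier_report")) report$declared else report
  unknown <- setdiff(declared, manifest$sample_id)
  if (length(unknown))
    stopf("apply_exclusions: unknown sample id(s) in outlier report: %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
  hit <- manifest$sample_id %in% declared & manifest$exclusion == "none"
  manifest$exclusion[hit] <- "outlier"
  excl <- manifest$exclusion != "none"
  summary <- data.frame(
    reason = c("missed_injection", "maternal_contamination", "outlier",
               "total", "excluded", "retained"),
    n = c(sum(manifest$exclusion == "missed_injection"),
          sum(manifest$exclusion == "maternal_contamination"),
          sum(manifest$exclusion == "outlier"),
          nrow(manifest), sum(excl), sum(!excl)),
    stringsAsFactors = FALSE)
  list(manifest = manifest, summary = summary)
}

#' Mark irrecoverable features and derive the species-level view
#'
#' Features in `drop_ids` are marked not retained. The species-level view
#' additionally excludes SIM-mode measures (which duplicate NL measures of
#' the same species with less structural resolution).
#'
#' @param annotation Feature annotation with `feature_id`, `mode`,
#'   `retained` columns.
#' @param drop_ids Feature ids to drop (subset of `feature_id`).
#' @return List with `annotation` (updated), `n_retained` (retained
#'   measures) and `n_species` (retained non-SIM measures).
#' @export
retain_features <- function(annotation, drop_ids = character(0)) {
  if (!all(c("feature_id", "mode") %in% names(annotation)))
    stopf("retain_features: annotation needs 'feature_id' and 'mode' columns")
  unknown <- setdiff(drop_ids, annotation$feature_id)
  if (length(unknown))
    stopf("retain_features: unknown feature id(s): %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
  if (!"retained" %in% names(annotation)) annotation$retained <- TRUE
  annotation$retained[annotation$feature_id %in% drop_ids] <- FALSE
  list(annotation = annotation,
       n_retained = sum(annotation$retained),
       n_species = sum(annotation$retained & annotation$mode != "SIM"))
}

#' Lipid class totals
#'
#' Sums species concentrations per class per sample. For the TG and TG(O)
#' classes only SIM-mode measures contribute (abundant but less
#' structurally resolved); every other class sums its non-SIM measures.
#' Only retained features contribute.
#'
#' @param matrix Samples x features concentration matrix.
#' @param annotation Feature annotation (`feature_id`, `class`, `mode`,
#'   `retained`).
#' @param sim_classes Classes whose totals are summed from SIM measures.
#' @return Samples x classes matrix of totals.
#' @export
compute_class_totals <- function(matrix, annotation,
                                 sim_classes = c("TG", "TG(O)")) {
  check_matrix(matrix)
  if (!all(c("feature_id", "class", "mode") %in% names(annotation)))
    stopf("compute_class_totals: annotation needs feature_id/class/mode columns")
  if (!"retained" %in% names(annotation)) annotation$retained <- TRUE
  anno <- annotation[annotation$feature_id %in% colnames(matrix) &
                       annotation$retained, ]
  classes <- unique(anno$class)
  out <- matrix(NA_real_, nrow(matrix), length(classes),
                dimnames = list(rownames(matrix), classes))
  for (cl in classes) {
    use <- if (cl %in% sim_classes) anno$mode == "SIM" else anno$mode != "SIM"
    ids <- anno$feature_id[anno$class == cl & use]
    if (!length(ids))
      stopf("compute_class_totals: class '%s' has no contributing features", cl)
    out[, cl] <- rowSums(matrix[, ids, drop = FALSE])
  }
  out
}
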