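# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_matrix <- function(x, name = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix (samples x features)", name)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("%s must carry sample ids as rownames and feature ids as colnames", name)
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stopf("%s has duplicated sample or feature ids", name)
  if (any(x < 0, na.rm = TRUE))
    stopf("%s contains negative concentrations", name)
  invisible(x)
}

check_manifest <- function(manifest, ids = NULL) {
  need <- c("sample_id", "role", "batch")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stopf("manifest is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$sample_id))
    stopf("manifest sample ids are not unique")
  if (!"exclusion" %in% names(manifest)) manifest$exclusion <- "none"
  if (!is.null(ids)) {
    miss <- setdiff(ids, manifest$sample_id)
    if (length(miss))
      stopf("sample id(s) absent from manifest: %s",
            paste(utils::head(miss, 5L), collapse = ", "))
  }
  manifest
}

# Sample-type grouping used for zero replacement and kNN imputation:
# biological samples group by timepoint x matrix, each QC role is its own
# group (imputation and detection-limit context must not mix pooled QC
# material with biological samples, nor serum with plasma).
sample_type_groups <- function(manifest) {
  tp <- if ("timepoint" %in% names(manifest)) as.character(manifest$timepoint) else ""
  mx <- if ("matrix" %in% names(manifest)) as.character(manifest$matrix) else ""
  grp <- ifelse(manifest$role == "biological",
                paste("bio", tp, mx, sep = "|"),
                paste("qc", manifest$role, sep = "|"))
  names(grp) <- manifest$sample_id
  grp
}

# log10 transform that requires strictly positive (or NA) input.
safe_log10 <- function(x, context) {
  bad <- !is.na(x) & x <= 0
  if (any(bad))
    stopf("%s: %d value(s) are zero or negative; run replace_zeros() first",
          context, sum(bad))
  log10(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
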