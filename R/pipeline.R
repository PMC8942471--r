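# End-to-end pipeline driver: simulate -> preprocess -> qc -> associate ->
# longitudinal, with a run manifest recording parameters, seeds and input
# hashes so every output is reproducible.

log_msg <- function(fmt, ...) message(sprintf(paste0("[lipidcohort] ", fmt), ...))

#' Run the full pipeline
#'
#' Executes the configured stages in order on a synthetic cohort (or on
#' files supplied in the config), writing every artifact as plain-text
#' tables plus a JSON run manifest with parameter provenance, seed and
#' input hashes. A stage failure leaves partial outputs in place together
#' with a `FAILED` marker file and returns a non-zero status.
#'
#' Config fields (all optional unless noted): `out_dir` (required), `seed`,
#' `cohort` (arguments for [cohort_config()]), `preprocess` (`k`,
#' `n_components`, `percentile`), `associate` (`preset` or `terms`,
#' `timepoint`), `longitudinal` (`k`, `restarts`, `paired_timepoints` =
#' two labels), `stages` (subset of simulate/preprocess/qc/associate/
#' longitudinal).
#'
#' @param config Configuration list or path to a YAML/JSON file.
#' @return Invisibly, a list with `status` (0 = success) and `artifacts`
#'   (named file paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$out_dir)) stopf("run_pipeline: config needs 'out_dir'")
  stages <- config$stages %||%
    c("simulate", "preprocess", "qc", "associate", "longitudinal")
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  if (!"simulate" %in% stages) {
    # validate inputs up front: fail before any output is written
    for (f in c("matrix", "manifest", "annotation", "covariates")) {
      if (is.null(config[[f]]))
        stopf("run_pipeline: config needs '%s' when simulate is skipped", f)
      if (!file.exists(config[[f]]))
        stopf("run_pipeline: %s file not found: %s", f, config[[f]])
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  status <- 0L

  run_stage <- function(name, fun) {
    log_msg("stage %s ...", name)
    t0 <- Sys.time()
    fun()
    log_msg("stage %s done (%.1fs)", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  result <- tryCatch({
    cohort <- NULL
    if ("simulate" %in% stages) {
      run_stage("simulate", function() {
        cc_args <- config$cohort %||% list()
        cc_args$seed <- cc_args$seed %||% seed
        cfg <- do.call(cohort_config, cc_args)
        cohort <<- generate_cohort(cfg)
        artifacts$matrix <<- write_concentration_matrix(
          cohort$matrix, file.path(out_dir, "matrix.csv"))
        artifacts$manifest <<- write_table_file(
          cohort$manifest, file.path(out_dir, "manifest.csv"))
        artifacts$annotation <<- write_table_file(
          cohort$annotation, file.path(out_dir, "annotation.csv"))
        artifacts$covariates <<- write_table_file(
          cohort$covariates, file.path(out_dir, "covariates.csv"))
        log_msg("simulated %d samples x %d features",
                nrow(cohort$matrix), ncol(cohort$matrix))
      })
    } else {
      cohort <- list(
        matrix = read_concentration_matrix(config$matrix),
        manifest = read_manifest(config$manifest),
        annotation = utils::read.table(config$annotation, header = TRUE,
                                       sep = sep_for(config$annotation),
                                       stringsAsFactors = FALSE),
        covariates = utils::read.table(config$covariates, header = TRUE,
                                       sep = sep_for(config$covariates),
                                       stringsAsFactors = FALSE))
    }
    mat <- cohort$matrix
    manifest <- cohort$manifest

    if ("preprocess" %in% stages) {
      run_stage("preprocess", function() {
        pp <- config$preprocess %||% list()
        mat <<- replace_zeros(mat, manifest)
        mat <<- harmonize_batches(mat, manifest)
        mat <<- impute_knn(mat, manifest, k = pp$k %||% 5L)
        report <- detect_outliers(mat, manifest,
                                  n_components = pp$n_components %||% 7L,
                                  percentile = pp$percentile %||% 0.95)
        excl <- apply_exclusions(manifest, report)
        manifest <<- excl$manifest
        artifacts$processed_matrix <<- write_concentration_matrix(
          mat, file.path(out_dir, "processed_matrix.csv"))
        artifacts$outliers <<- write_outlier_report(
          report, file.path(out_dir, "outliers"))
        artifacts$exclusions <<- write_table_file(
          excl$summary, file.path(out_dir, "exclusion_summary.tsv"))
        artifacts$manifest_processed <<- write_table_file(
          manifest, file.path(out_dir, "manifest_processed.csv"))
        log_msg("samples: %d total, %d retained; %d declared outliers",
                nrow(manifest), sum(manifest$exclusion == "none"),
                length(report$declared))
      })
    }
    if ("qc" %in% stages) {
      run_stage("qc", function() {
        cv <- compute_cv(mat, manifest, role = "PQC")
        artifacts$cv_report <<- write_table_file(
          data.frame(feature_id = names(cv$cv), cv_percent = cv$cv),
          file.path(out_dir, "cv_report.tsv"))
        jsonlite::write_json(list(median_cv = cv$median_cv,
                                  frac_below_20 = cv$frac_below_20,
                                  n_samples = cv$n_samples),
                             file.path(out_dir, "cv_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        artifacts$cv_summary <<- file.path(out_dir, "cv_summary.json")
        log_msg("median PQC CV %.1f%%; %.1f%% of features < 20%%",
                cv$median_cv, 100 * cv$frac_below_20)
      })
    }
    if ("associate" %in% stages) {
      run_stage("associate", function() {
        ac <- config$associate %||% list()
        tp <- ac$timepoint %||% "birth"
        keep <- manifest$sample_id[manifest$role == "biological" &
                                     manifest$exclusion == "none" &
                                     manifest$timepoint == tp]
        sub <- mat[rownames(mat) %in% keep, , drop = FALSE]
        fit <- fit_lipid_regressions(sub, cohort$covariates,
                                     terms = ac$terms,
                                     preset = if (is.null(ac$terms))
                                       ac$preset %||% "birth")
        artifacts$associations <<- write_table_file(
          fit, file.path(out_dir, sprintf("associations_%s.tsv", tp)))
        log_msg("fitted %d features x %d contrasts at %s (n = %d)",
                length(unique(fit$feature_id)),
                length(unique(fit$contrast)), tp, max(fit$n))
      })
    }
    if ("longitudinal" %in% stages) {
      run_stage("longitudinal", function() {
        lc <- config$longitudinal %||% list()
        tc <- cluster_trajectories(mat, manifest,
                                   k = lc$k %||% 10L, seed = seed,
                                   restarts = lc$restarts %||% 10L)
        artifacts$clusters <<- write_table_file(
          data.frame(feature_id = names(tc$assignments),
                     cluster = tc$assignments,
                     medoid = names(tc$assignments) %in% tc$medoid_ids),
          file.path(out_dir, "trajectory_clusters.tsv"))
        artifacts$dtw <<- write_table_file(
          data.frame(feature_id = rownames(tc$dmatrix), tc$dmatrix,
                     check.names = FALSE),
          file.path(out_dir, "dtw_dissimilarity.tsv"))
        pt <- lc$paired_timepoints %||% utils::head(
          unique(manifest$timepoint[manifest$role == "biological"]), 2L)
        bio <- manifest[manifest$role == "biological" &
                          manifest$exclusion == "none", ]
        s1 <- bio[bio$timepoint == pt[1], c("subject_id", "sample_id")]
        s2 <- bio[bio$timepoint == pt[2], c("subject_id", "sample_id")]
        pairing <- merge(s1, s2, by = "subject_id")
        names(pairing)[2:3] <- c("sample_1", "sample_2")
        pc <- paired_compare(mat, pairing, test = "wilcoxon")
        artifacts$paired <<- write_table_file(
          pc, file.path(out_dir,
                        sprintf("paired_%s_vs_%s.tsv", pt[1], pt[2])))
        log_msg("clustered %d trajectories into %d clusters; %d pairs %s vs %s",
                length(tc$assignments), tc$k, nrow(pairing), pt[1], pt[2])
      })
    }

    inputs <- unlist(artifacts[c("matrix", "manifest", "annotation",
                                 "covariates")])
    run_manifest <- list(
      package = "lipidcohort",
      version = as.character(utils::packageVersion("lipidcohort")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed, stages = stages, config = config,
      input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
      artifacts = lapply(artifacts, function(a) unname(a)))
    jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    artifacts$run_manifest <- file.path(out_dir, "run_manifest.json")
    0L
  }, error = function(e) {
    writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
    log_msg("pipeline FAILED: %s", conditionMessage(e))
    1L
  })
  invisible(list(status = result, artifacts = artifacts))
}
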