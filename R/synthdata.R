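# Synthetic cohort generator.
#
# Emulates the structure of a multi-batch targeted lipidomics run on a
# longitudinal birth cohort: log10-normal lipid baselines spanning several
# orders of magnitude, per-timepoint trajectory offsets, planted covariate
# effects, batch location/scale perturbations, interleaved pooled-QC
# samples, below-detection censoring, missingness and gross outliers.

#' Default lipid class vocabulary used by the generator
#'
#' A compact set of lipid classes covering the three forest-plot categories
#' (sphingolipids, phospholipids, other lipids), including the ether-linked
#' triglyceride class `TG(O)` whose species are strongly elevated in
#' breastfed infants, and the `TG`/`TG(O)` classes whose totals are summed
#' from SIM-mode measures.
#'
#' @return Character vector of class names.
#' @export
lipid_classes <- function() {
  c("SM", "Cer", "HexCer", "GM3",                       # sphingolipids
    "PC", "PE", "PI", "LPC", "LPE", "PE(P)", "PC(O)",   # phospholipids
    "TG", "TG(O)", "DG", "CE", "FFA", "AC", "COH")      # other lipids
}

#' Build a cohort generator configuration
#'
#' Assembles and validates the parameters of [generate_cohort()]. Defaults
#' reproduce the run design of a large multi-batch infant cohort study:
#' five time-point groups (maternal serum at 28 weeks' gestation, cord serum
#' at birth, plasma at 6 months, 12 months and 4 years), 11 analytical
#' batches, one pooled plasma QC (PQC) and one technical QC (TQC) per 20
#' biological samples and one reference-material (NIST) sample per 40.
#'
#' @param n_subjects Number of mother-child dyads; each contributes one
#'   sample per time point.
#' @param timepoints Ordered character vector of time-point labels. The
#'   first is treated as the maternal antenatal draw, the second as cord
#'   serum at birth; serum/plasma matrix is assigned accordingly.
#' @param n_batches Number of analytical batches.
#' @param pqc_interval,tqc_interval,nist_interval Biological samples per
#'   PQC, TQC and NIST sample respectively.
#' @param n_features Number of lipid features.
#' @param class_map Optional character vector (length `n_features`) giving
#'   the lipid class of each feature; defaults to a cyclic assignment over
#'   [lipid_classes()].
#' @param effects List of planted effects, each built by [planted_effect()].
#' @param time_profiles Optional `n_features x length(timepoints)` matrix of
#'   log10 offsets describing each feature's age trajectory. Default: a
#'   seeded random-walk profile (step sd 0.15 log10) so that features carry
#'   distinct age trends.
#' @param zero_rate Fraction of each feature's biological concentration
#'   distribution censored below the detection threshold (recorded as 0).
#' @param missing_rate Probability an entry is missing (`NA`), independent
#'   of censoring.
#' @param outlier_spec List with `n` (count) and `scale` (multiplier) of
#'   gross outlier samples injected via [inject_outliers()].
#' @param batch_shift_sd Standard deviation (log10) of the per-batch,
#'   per-feature additive location shift. Drawn shifts are median-centred
#'   across batches per feature (identifiability convention).
#' @param batch_scale_sd Standard deviation (log10) of the per-batch
#'   multiplicative scale factor `10^N(0, batch_scale_sd)` applied about the
#'   batch biological median. Drawn factors are normalized to mean 1.
#' @param noise_sd Length-2 range from which each feature's biological
#'   residual sd (log10) is drawn uniformly, or a single value used for all
#'   features. `c(0, 0)` gives noiseless data.
#' @param qc_noise_sd Per-feature replicate sd (log10) of pooled-QC
#'   measurements. `NULL` (default) draws per-feature values from a
#'   log-normal centred at 0.044 log10 units (about 10% CV, with ~93% of
#'   features below 20% CV, matching routine targeted-lipidomics precision).
#'   A scalar fixes the sd for every feature (0 = noiseless QCs).
#' @param seed Integer seed; the seed fully determines the generated cohort.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [planted_effect()]
#' @export
cohort_config <- function(n_subjects = 200L,
                          timepoints = c("M28", "birth", "6m", "12m", "4y"),
                          n_batches = 11L,
                          pqc_interval = 20L,
                          tqc_interval = 20L,
                          nist_interval = 40L,
                          n_features = 100L,
                          class_map = NULL,
                          effects = list(),
                          time_profiles = NULL,
                          zero_rate = 0.01,
                          missing_rate = 0.005,
                          outlier_spec = list(n = 0L, scale = 100),
                          batch_shift_sd = 0.05,
                          batch_scale_sd = 0.05,
                          noise_sd = c(0.10, 0.20),
                          qc_noise_sd = NULL,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), timepoints = timepoints,
              n_batches = as.integer(n_batches),
              pqc_interval = as.integer(pqc_interval),
              tqc_interval = as.integer(tqc_interval),
              nist_interval = as.integer(nist_interval),
              n_features = as.integer(n_features), class_map = class_map,
              effects = effects, time_profiles = time_profiles,
              zero_rate = zero_rate, missing_rate = missing_rate,
              outlier_spec = outlier_spec,
              batch_shift_sd = batch_shift_sd,
              batch_scale_sd = batch_scale_sd,
              noise_sd = if (length(noise_sd) == 1L) rep(noise_sd, 2L) else noise_sd,
              qc_noise_sd = qc_noise_sd, seed = as.integer(seed))

  for (f in c("n_subjects", "n_batches", "pqc_interval", "tqc_interval",
              "nist_interval", "n_features"))
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stopf("cohort_config: '%s' must be a positive count", f)
  if (anyDuplicated(cfg$timepoints) || length(cfg$timepoints) < 1L)
    stopf("cohort_config: 'timepoints' must be unique, non-empty labels")
  for (f in c("zero_rate", "missing_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stopf("cohort_config: '%s' must lie in [0, 1]", f)
  for (f in c("batch_shift_sd", "batch_scale_sd"))
    if (cfg[[f]] < 0) stopf("cohort_config: '%s' must be >= 0", f)
  if (any(cfg$noise_sd < 0)) stopf("cohort_config: 'noise_sd' must be >= 0")
  if (!is.null(cfg$class_map) && length(cfg$class_map) != cfg$n_features)
    stopf("cohort_config: 'class_map' must have length n_features")
  if (!is.null(cfg$time_profiles) &&
      !identical(dim(cfg$time_profiles),
                 c(cfg$n_features, length(cfg$timepoints))))
    stopf("cohort_config: 'time_profiles' must be n_features x n_timepoints")
  if (!is.numeric(cfg$outlier_spec$n %||% 0) ||
      (cfg$outlier_spec$scale %||% 1) <= 0)
    stopf("cohort_config: 'outlier_spec' needs counts n >= 0 and scale > 0")
  for (e in cfg$effects) {
    if (!inherits(e, "planted_effect"))
      stopf("cohort_config: every element of 'effects' must come from planted_effect()")
  }
  structure(cfg, class = "cohort_config")
}

#' Describe a planted covariate effect
#'
#' @param features Integer indices or feature ids the effect applies to.
#' @param covariate Name of a covariate column (e.g. `"gestational_age"`,
#'   `"breastfeeding_6m"`).
#' @param type `"slope"` adds `magnitude * covariate` to the log10
#'   concentration (per covariate unit); `"fold"` multiplies concentrations
#'   by `magnitude` in the `"y"` (or non-reference) group of a two-level
#'   covariate.
#' @param magnitude Finite effect size; for `"fold"` it must be > 0.
#' @param timepoints Time points at which the effect is active (`NULL` =
#'   all).
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(features, covariate,
                           type = c("slope", "fold"),
                           magnitude, timepoints = NULL) {
  type <- match.arg(type)
  if (!is.finite(magnitude))
    stopf("planted_effect: 'magnitude' must be finite")
  if (type == "fold" && magnitude <= 0)
    stopf("planted_effect: fold 'magnitude' must be > 0")
  structure(list(features = features, covariate = covariate, type = type,
                 magnitude = magnitude, timepoints = timepoints),
            class = "planted_effect")
}

# Subject-level covariates. Gestational age (days) and birth weight (kg)
# are drawn jointly with correlation 0.45; mode-of-birth proportions follow
# the four-level breakdown of a typical Australian birth cohort
# (VB 525 : assisted VB 214 : scheduled CS 178 : unscheduled CS 155).
simulate_covariates <- function(n) {
  r <- 0.45
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  mob_p <- c(VB = 525, `assisted VB` = 214, `scheduled CS` = 178,
             `unscheduled CS` = 155) / 1072
  mob <- sample(names(mob_p), n, replace = TRUE, prob = mob_p)
  labour <- stats::rlnorm(n, log(6), 0.6)
  labour[mob == "scheduled CS"] <- 0
  bf6 <- ifelse(stats::runif(n) < 0.70, "y", "n")
  bf12 <- ifelse(bf6 == "y",
                 ifelse(stats::runif(n) < 0.65, "y", "n"),
                 ifelse(stats::runif(n) < 0.05, "y", "n"))
  data.frame(
    subject_id = sprintf("C%04d", seq_len(n)),
    gestational_age = round(278 + 9 * z1, 1),
    birth_weight = round(pmax(1.2, 3.5 + 0.5 * z2), 3),
    mode_of_birth = mob,
    labour_hours = round(labour, 2),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.49, 0.51)),
    maternal_bmi = round(pmax(16, stats::rnorm(n, 25.5, 4.5)), 1),
    gdm = ifelse(stats::runif(n) < 0.06, "y", "n"),
    maternal_education = sample(c("secondary", "tertiary", "postgraduate"),
                                n, replace = TRUE, prob = c(0.35, 0.45, 0.20)),
    maternal_age = round(stats::rnorm(n, 32, 4.5), 1),
    birth_order = sample(1:3, n, replace = TRUE, prob = c(0.45, 0.35, 0.20)),
    breastfeeding_6m = bf6,
    breastfeeding_12m = bf12,
    stringsAsFactors = FALSE)
}

default_annotation <- function(n_features, class_map = NULL) {
  classes <- class_map %||% rep_len(lipid_classes(), n_features)
  mode <- rep("standard", n_features)
  # TG and TG(O) are measured as both neutral-loss and SIM peaks; alternate
  # so class totals have SIM measures to sum and species-level views have
  # NL measures to keep.
  for (cl in c("TG", "TG(O)")) {
    idx <- which(classes == cl)
    if (length(idx)) mode[idx] <- rep(c("NL", "SIM"), length.out = length(idx))
  }
  counter <- stats::ave(seq_len(n_features), classes, FUN = seq_along)
  data.frame(
    feature_id = sprintf("F%03d", seq_len(n_features)),
    class = classes,
    species = sprintf("%s(%d:%d)%s", classes, 30 + counter, counter %% 7,
                      ifelse(mode == "standard", "", paste0(" [", mode, "]"))),
    mode = mode,
    retained = TRUE,
    stringsAsFactors = FALSE)
}

nominal_age_days <- function(timepoints) {
  known <- c(M28 = -84, birth = 0, "6m" = 183, "12m" = 365, "4y" = 1461)
  ifelse(timepoints %in% names(known), known[timepoints],
         365 * seq_along(timepoints))
}

#' Generate a seeded synthetic lipidomics cohort
#'
#' Draws a full multi-batch cohort: biological samples follow per-feature
#' log10-normal baselines (means spanning roughly four orders of magnitude)
#' plus per-timepoint trajectory offsets and planted covariate effects;
#' pooled-QC samples are noisy replicates of the pooled biological profile
#' (per-feature median of the biological samples); batch location/scale
#' perturbations are applied to all samples of a batch on the log10 scale;
#' below-detection values are censored to 0 and missing entries to `NA`.
#' The same seed always reproduces the identical cohort.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `lipid_cohort` with elements `matrix` (samples x
#'   features concentration matrix), `manifest`, `annotation`, `covariates`
#'   (per-sample covariate table including `batch` and `child_age_days`),
#'   `outlier_ids` (ids of injected gross outliers) and `truth` (generative
#'   parameters: baseline means, time profiles, pool profile, batch shifts
#'   and scales, per-feature noise sds).
#' @examples
#' cfg <- cohort_config(n_subjects = 20, n_batches = 2, n_features = 10,
#'                      zero_rate = 0, missing_rate = 0, seed = 7)
#' coh <- generate_cohort(cfg)
#' dim(coh$matrix)
#' table(coh$manifest$role)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stopf("generate_cohort: 'config' must come from cohort_config()")
  with_seed(config$seed, {
    nt <- length(config$timepoints)
    nf <- config$n_features
    ns <- config$n_subjects

    covs <- simulate_covariates(ns)
    anno <- default_annotation(nf, config$class_map)

    mu <- stats::runif(nf, -1, 3)                      # baseline log10 means
    sdj <- stats::runif(nf, config$noise_sd[1], config$noise_sd[2])
    profiles <- config$time_profiles
    if (is.null(profiles)) {
      steps <- matrix(stats::rnorm(nf * nt, 0, 0.15), nf, nt)
      steps[, 1] <- 0
      profiles <- t(apply(steps, 1L, cumsum))
      if (nt == 1L) profiles <- matrix(profiles, nf, 1L)
    }
    dimnames(profiles) <- list(anno$feature_id, config$timepoints)

    # biological samples: one per subject per timepoint
    grid <- expand.grid(subject = seq_len(ns), tp = seq_len(nt),
                        KEEP.OUT.ATTRS = FALSE)
    bio_ids <- sprintf("S%04d_%s", grid$subject, config$timepoints[grid$tp])

    L <- matrix(mu, nrow(grid), nf, byrow = TRUE) +
      t(profiles[, grid$tp, drop = FALSE])
    for (e in config$effects) {
      fidx <- if (is.character(e$features)) match(e$features, anno$feature_id)
              else as.integer(e$features)
      if (anyNA(fidx) || any(fidx < 1L) || any(fidx > nf))
        stopf("generate_cohort: planted effect names unknown feature(s)")
      rows <- if (is.null(e$timepoints)) rep(TRUE, nrow(grid))
              else config$timepoints[grid$tp] %in% e$timepoints
      if (!e$covariate %in% names(covs))
        stopf("generate_cohort: planted effect covariate '%s' unknown", e$covariate)
      x <- covs[[e$covariate]][grid$subject]
      add <- if (e$type == "slope") e$magnitude * as.numeric(x)
             else log10(e$magnitude) * as.numeric(x == "y" | x == 1)
      L[rows, fidx] <- L[rows, fidx] + add[rows]
    }
    L <- L + matrix(stats::rnorm(nrow(grid) * nf, 0, 1), nrow(grid), nf) *
      matrix(sdj, nrow(grid), nf, byrow = TRUE)
    dimnames(L) <- list(bio_ids, anno$feature_id)

    # pooled-QC profile: the pool is made from the study samples themselves,
    # so its profile is the per-feature median of the biological log10 values
    pool <- apply(L, 2L, stats::median)
    qc_sd <- if (is.null(config$qc_noise_sd))
      stats::rlnorm(nf, log(0.044), 0.45) else rep(config$qc_noise_sd, nf)

    # batch layout: biological samples shuffled, then split into batches
    ord <- sample(nrow(L))
    batch_of <- integer(nrow(L))
    chunk <- rep(seq_len(config$n_batches),
                 each = ceiling(nrow(L) / config$n_batches))[seq_len(nrow(L))]
    batch_of[ord] <- chunk

    qc_rows <- list(); qc_meta <- list()
    for (b in seq_len(config$n_batches)) {
      nb <- sum(batch_of == b)
      n_pqc <- max(2L, as.integer(ceiling(nb / config$pqc_interval)))
      n_tqc <- max(1L, as.integer(ceiling(nb / config$tqc_interval)))
      n_nist <- max(1L, as.integer(ceiling(nb / config$nist_interval)))
      mk <- function(role, n, sd_mult, interval, frac, offset = 0) {
        ids <- sprintf("%s_B%02d_%02d", role, b, seq_len(n))
        vals <- matrix(pool + offset, n, nf, byrow = TRUE) +
          matrix(stats::rnorm(n * nf), n, nf) *
          matrix(qc_sd * sd_mult, n, nf, byrow = TRUE)
        dimnames(vals) <- list(ids, anno$feature_id)
        qc_rows[[length(qc_rows) + 1L]] <<- vals
        qc_meta[[length(qc_meta) + 1L]] <<- data.frame(
          sample_id = ids, subject_id = NA_character_, role = role,
          batch = sprintf("B%02d", b), timepoint = "pool",
          matrix = "plasma", exclusion = "none",
          pos = (seq_len(n) - 0.5) * interval + frac,  # run-order interleave
          stringsAsFactors = FALSE)
      }
      mk("PQC", n_pqc, 1, config$pqc_interval, 0.25)
      mk("TQC", n_tqc, 0.6, config$tqc_interval, 0.50)  # instrument-only noise
      mk("NIST", n_nist, 1, config$nist_interval, 0.75, offset = 0.05)
    }

    # first timepoint = maternal serum, second = cord serum, rest plasma
    mx <- rep("plasma", nt)
    if (nt >= 1L) mx[1] <- "serum"
    if (nt >= 2L) mx[2] <- "serum"
    pos_in_batch <- stats::ave(seq_len(nrow(L)), batch_of, FUN = seq_along)
    bio_manifest <- data.frame(
      sample_id = bio_ids,
      subject_id = covs$subject_id[grid$subject],
      role = "biological",
      batch = sprintf("B%02d", batch_of),
      timepoint = config$timepoints[grid$tp],
      matrix = mx[grid$tp],
      exclusion = "none",
      pos = pos_in_batch,
      stringsAsFactors = FALSE)

    manifest <- rbind(bio_manifest, do.call(rbind, qc_meta))
    Lall <- rbind(L, do.call(rbind, qc_rows))

    # run order: batches sequential, QC samples interleaved every interval
    manifest <- manifest[order(manifest$batch, manifest$pos), ]
    manifest$pos <- NULL
    rownames(manifest) <- NULL
    Lall <- Lall[manifest$sample_id, , drop = FALSE]

    # batch perturbations (identifiability convention: per-feature shifts
    # median-centred across batches, scale factors normalized to mean 1)
    shifts <- matrix(0, config$n_batches, nf,
                     dimnames = list(sprintf("B%02d", seq_len(config$n_batches)),
                                     anno$feature_id))
    scales <- rep(1, config$n_batches)
    names(scales) <- rownames(shifts)
    if (config$n_batches > 1L) {
      if (config$batch_shift_sd > 0) {
        shifts[] <- stats::rnorm(length(shifts), 0, config$batch_shift_sd)
        shifts <- sweep(shifts, 2L, apply(shifts, 2L, stats::median))
      }
      if (config$batch_scale_sd > 0) {
        scales <- 10^stats::rnorm(config$n_batches, 0, config$batch_scale_sd)
        scales <- scales / mean(scales)
        names(scales) <- rownames(shifts)
      }
    }
    conc <- 10^Lall
    if (any(shifts != 0) || any(scales != 1))
      conc <- inject_batch_effects(conc, manifest, shifts, scales)

    # below-detection censoring: per-feature threshold at the zero_rate
    # quantile of the biological concentration distribution
    if (config$zero_rate > 0) {
      bio <- manifest$role == "biological"
      thr <- apply(conc[bio, , drop = FALSE], 2L, stats::quantile,
                   probs = config$zero_rate, type = 7)
      conc <- sweep(conc, 2L, thr, function(v, t) ifelse(v < t, 0, v))
    }
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(conc)) < config$missing_rate,
                     nrow(conc), ncol(conc))
      conc[mask] <- NA_real_
    }

    # per-sample covariate table
    sample_covs <- merge(manifest[manifest$role == "biological",
                                  c("sample_id", "subject_id", "timepoint", "batch")],
                         covs, by = "subject_id", sort = FALSE)
    age <- nominal_age_days(sample_covs$timepoint)
    jitter <- ifelse(sample_covs$timepoint %in% c("M28", "birth"), 0,
                     round(stats::rnorm(nrow(sample_covs), 0, 7)))
    sample_covs$child_age_days <- age + jitter
    sample_covs <- sample_covs[match(bio_manifest$sample_id, sample_covs$sample_id), ]
    rownames(sample_covs) <- NULL

    out <- list(matrix = conc, manifest = manifest, annotation = anno,
                covariates = sample_covs, outlier_ids = character(0),
                truth = list(mu = stats::setNames(mu, anno$feature_id),
                             noise_sd = stats::setNames(sdj, anno$feature_id),
                             time_profiles = profiles, pool = pool,
                             batch_shifts = shifts, batch_scales = scales,
                             qc_noise_sd = stats::setNames(qc_sd, anno$feature_id)))
    n_out <- as.integer(config$outlier_spec$n %||% 0)
    if (n_out > 0L) {
      oo <- inject_outliers(out$matrix, out$manifest, n = n_out,
                            scale = config$outlier_spec$scale %||% 100,
                            seed = config$seed + 1L)
      out$matrix <- oo$matrix
      out$outlier_ids <- oo$sample_ids
    }
    class(out) <- "lipid_cohort"
    out
  })
}

#' @export
print.lipid_cohort <- function(x, ...) {
  cat(sprintf("Synthetic lipidomics cohort: %d samples x %d features\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(table(role = x$manifest$role))
  cat(sprintf("batches: %d; timepoints: %s\n",
              length(unique(x$manifest$batch)),
              paste(unique(x$manifest$timepoint[x$manifest$role == "biological"]),
                    collapse = ", ")))
  invisible(x)
}

#' Apply known batch location/scale perturbations
#'
#' Perturbs a concentration matrix on the log10 scale: for every sample of
#' batch `b` and feature `f`, values become
#' `c_bf + scale_b * (x - c_bf) + shift_bf` where `c_bf` is the batch's
#' biological-sample median. This is exactly the structure
#' [harmonize_batches()] removes, enabling exact-recovery tests.
#'
#' @param matrix Samples x features concentration matrix (positive values).
#' @param manifest Sample manifest with `batch` and `role` columns.
#' @param shifts Numeric matrix (batches x features) of additive log10
#'   shifts, rownames = batch ids; or a single named vector recycled across
#'   features.
#' @param scales Named numeric vector of per-batch scale factors.
#' @return Perturbed concentration matrix.
#' @export
inject_batch_effects <- function(matrix, manifest, shifts, scales) {
  check_matrix(matrix)
  manifest <- check_manifest(manifest, rownames(matrix))
  manifest <- manifest[match(rownames(matrix), manifest$sample_id), ]
  L <- suppressWarnings(log10(matrix))    # zeros/NA pass through untouched
  for (b in unique(manifest$batch)) {
    rows <- manifest$batch == b
    brow <- if (is.matrix(shifts)) shifts[b, ] else rep(shifts[[b]], ncol(L))
    sb <- scales[[b]]
    bio <- rows & manifest$role == "biological"
    ctr <- apply(L[bio, , drop = FALSE], 2L,
                 function(v) stats::median(v[is.finite(v)], na.rm = TRUE))
    sub <- L[rows, , drop = FALSE]
    sub <- sweep(sweep(sub, 2L, ctr), 2L, rep(sb, ncol(L)), `*`)
    sub <- sweep(sweep(sub, 2L, ctr, `+`), 2L, brow, `+`)
    L[rows, ] <- sub
  }
  out <- 10^L
  out[!is.na(matrix) & matrix == 0] <- 0
  out[is.na(matrix)] <- NA_real_
  out
}

#' Inject gross outlier samples
#'
#' Multiplies every observed value of `n` randomly chosen biological
#' samples by `scale`, emulating gross sample-handling failures used to
#' exercise the dual-criterion outlier detector.
#'
#' @param matrix Samples x features concentration matrix.
#' @param manifest Sample manifest (only biological samples are eligible).
#' @param n Number of samples to corrupt; must be below the biological
#'   sample count.
#' @param scale Positive multiplier applied to all observed values.
#' @param seed Integer seed; the same seed always selects the same samples.
#' @return List with `matrix` (perturbed copy) and `sample_ids` (the chosen
#'   ids, in lexicographic order).
#' @export
inject_outliers <- function(matrix, manifest, n, scale, seed = 1L) {
  check_matrix(matrix)
  manifest <- check_manifest(manifest, rownames(matrix))
  if (scale <= 0) stopf("inject_outliers: 'scale' must be > 0")
  bio <- sort(manifest$sample_id[manifest$role == "biological"])
  if (n >= length(bio))
    stopf("inject_outliers: n (%d) must be below the biological sample count (%d)",
          n, length(bio))
  ids <- with_seed(seed, sort(sample(bio, n)))
  out <- matrix
  rows <- rownames(out) %in% ids
  out[rows, ] <- out[rows, ] * scale
  list(matrix = out, sample_ids = ids)
}
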