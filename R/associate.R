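# Per-lipid covariate-adjusted association engine.
#
# One OLS fit per lipid feature of log10 concentration on the requested
# covariates; coefficients are reported per term with t-based 95% CIs,
# converted to percentage change via (10^beta - 1) * 100, and BH-adjusted
# per model term across features.

#' Named covariate presets for the standard models
#'
#' `"birth"` is the cord-serum model (gestational age, birth weight, mode
#' of birth, duration of labour, sex, maternal BMI, GDM, maternal
#' education, maternal age, birth order, run batch). The breastfeeding
#' models adjust for child age and sex plus the maternal covariates, with
#' gestational age included at 6 months only (gestational age influences
#' lipids at 6 but not 12 months); batch is included for symmetry.
#'
#' @return Named list of character vectors of covariate names.
#' @export
covariate_presets <- function() {
  list(
    birth = c("gestational_age", "birth_weight", "mode_of_birth",
              "labour_hours", "sex", "maternal_bmi", "gdm",
              "maternal_education", "maternal_age", "birth_order", "batch"),
    breastfeeding_6m = c("breastfeeding_6m", "child_age_days", "sex",
                         "birth_weight", "gestational_age", "maternal_bmi",
                         "gdm", "maternal_education", "birth_order", "batch"),
    breastfeeding_12m = c("breastfeeding_12m", "child_age_days", "sex",
                          "birth_weight", "maternal_bmi", "gdm",
                          "maternal_education", "birth_order", "batch"))
}

# Documented reference levels: unassisted vaginal birth for mode of birth,
# female for sex, "n" for yes/no covariates.
ref_levels <- c(mode_of_birth = "VB", sex = "female", gdm = "n",
                breastfeeding_6m = "n", breastfeeding_12m = "n")

prepare_design_frame <- function(covariates, terms) {
  miss <- setdiff(terms, names(covariates))
  if (length(miss))
    stopf("fit_lipid_regressions: covariate column(s) not found: %s",
          paste(miss, collapse = ", "))
  df <- covariates[, terms, drop = FALSE]
  for (v in names(df)) {
    if (is.character(df[[v]]) || is.logical(df[[v]])) df[[v]] <- factor(df[[v]])
    if (is.factor(df[[v]]) && v %in% names(ref_levels) &&
        ref_levels[[v]] %in% levels(df[[v]]))
      df[[v]] <- stats::relevel(df[[v]], ref_levels[[v]])
  }
  df
}

#' Fit per-lipid covariate-adjusted linear models
#'
#' Ordinary least squares of log10 concentration on the requested
#' covariates, one fit per feature. Rows with a missing covariate or a
#' missing/zero concentration are dropped per fit (listwise deletion), and
#' the effective n is recorded. Confidence intervals are t-based.
#'
#' @param matrix Samples x features concentration matrix (the samples to
#'   model, e.g. one time point's biological samples). Zeros must have been
#'   replaced.
#' @param covariates Per-sample covariate table with a `sample_id` column;
#'   every sample in `matrix` must have a row.
#' @param terms Character vector of covariate names to adjust for, or
#' @param preset a name from [covariate_presets()] (used if `terms` is
#'   `NULL`).
#' @param conf_level Confidence level for the CIs (default 0.95).
#' @return A data frame of class `association_result`, one row per feature
#'   x design contrast: `feature_id`, `term` (covariate), `contrast`
#'   (design column), `beta`, `se`, `ci_lo`, `ci_hi`, `pct_change`,
#'   `pct_lo`, `pct_hi`, `p`, `p_adj` (BH per contrast across features),
#'   `n`.
#' @export
fit_lipid_regressions <- function(matrix, covariates, terms = NULL,
                                  preset = NULL, conf_level = 0.95) {
  check_matrix(matrix)
  if (is.null(terms)) {
    if (is.null(preset)) stopf("fit_lipid_regressions: give 'terms' or 'preset'")
    terms <- covariate_presets()[[match.arg(preset, names(covariate_presets()))]]
  }
  if (!"sample_id" %in% names(covariates))
    stopf("fit_lipid_regressions: covariates need a 'sample_id' column")
  idx <- match(rownames(matrix), covariates$sample_id)
  if (anyNA(idx))
    stopf("fit_lipid_regressions: no covariate row for sample(s): %s",
          paste(utils::head(rownames(matrix)[is.na(idx)], 5L), collapse = ", "))
  df <- prepare_design_frame(covariates[idx, , drop = FALSE], terms)
  cc <- stats::complete.cases(df)

  single <- vapply(df, function(v) is.factor(v) &&
                     length(unique(v[cc])) < 2L, logical(1))
  if (any(single))
    stopf("fit_lipid_regressions: constant factor term(s): %s",
          paste(names(df)[single], collapse = ", "))

  Y <- suppressWarnings(log10(matrix))
  Y[!is.na(matrix) & matrix <= 0] <- NA   # zeros cannot enter the log model
  res <- list()
  masks <- apply(!is.na(Y[cc, , drop = FALSE]), 2L, paste, collapse = "")
  for (key in unique(masks)) {
    feats <- names(masks)[masks == key]
    rows <- which(cc)[!is.na(Y[cc, feats[1]])]
    sub <- df[rows, , drop = FALSE]
    X <- stats::model.matrix(~ ., data = sub)
    if (nrow(X) <= ncol(X))
      stopf("fit_lipid_regressions: n = %d rows cannot identify %d parameters",
            nrow(X), ncol(X))
    fit <- stats::lm.fit(X, Y[rows, feats, drop = FALSE])
    if (fit$rank < ncol(X)) {
      aliased <- colnames(X)[is.na(stats::coef(fit))]
      if (!length(aliased)) aliased <- colnames(X)
      stopf("fit_lipid_regressions: rank-deficient design; collinear term(s): %s",
            paste(aliased, collapse = ", "))
    }
    B <- fit$coefficients
    if (is.null(dim(B))) B <- cbind(B)
    xtx_inv_diag <- diag(chol2inv(qr.R(fit$qr)))[order(fit$qr$pivot)]
    dfres <- nrow(X) - ncol(X)
    E <- as.matrix(fit$residuals)
    s2 <- colSums(E^2) / dfres
    SE <- sqrt(outer(xtx_inv_diag, s2))
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, dfres)
    Tm <- B / SE
    P <- 2 * stats::pt(-abs(Tm), dfres)
    assign <- attr(X, "assign")
    labels <- c("(Intercept)", attr(stats::terms(~ ., data = sub), "term.labels"))
    keep <- which(assign > 0L)
    for (ci in keep) {
      res[[length(res) + 1L]] <- data.frame(
        feature_id = feats,
        term = labels[assign[ci] + 1L],
        contrast = colnames(X)[ci],
        beta = B[ci, ], se = SE[ci, ],
        ci_lo = B[ci, ] - tcrit * SE[ci, ],
        ci_hi = B[ci, ] + tcrit * SE[ci, ],
        p = P[ci, ], n = nrow(X),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$feature_id, colnames(matrix)), out$contrast), ]
  out$pct_change <- beta_to_percent_change(out$beta)
  out$pct_lo <- beta_to_percent_change(out$ci_lo)
  out$pct_hi <- beta_to_percent_change(out$ci_hi)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)          # zero-residual fits have undefined 0/0 tests
  out$p_adj[ok] <- bh_adjust(out$p[ok], out$contrast[ok])
  rownames(out) <- NULL
  out <- out[, c("feature_id", "term", "contrast", "beta", "se", "ci_lo",
                 "ci_hi", "pct_change", "pct_lo", "pct_hi", "p", "p_adj", "n")]
  class(out) <- c("association_result", "data.frame")
  out
}

#' Convert a log10-scale coefficient to percentage change
#'
#' `(10^beta - 1) * 100`: the percent difference in concentration per unit
#' of the model term. Applied elementwise (CI bounds included).
#'
#' @param beta Finite numeric vector of log10-scale coefficients.
#' @return Percentage change(s).
#' @examples
#' beta_to_percent_change(c(0, 1, 0.1))   # 0, 900, 25.89254
#' @export
beta_to_percent_change <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta)))
    stopf("beta_to_percent_change: 'beta' must be finite numeric")
  (10^beta - 1) * 100
}

#' Benjamini-Hochberg adjustment, per model term
#'
#' Step-up false-discovery-rate adjustment applied within each term group
#' across features.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @param grouping Optional grouping vector (e.g. the model term of each
#'   p-value); adjustment is performed within groups.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues, grouping = NULL) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1))
    stopf("bh_adjust: p-values must lie in [0, 1]")
  if (is.null(grouping)) return(stats::p.adjust(pvalues, method = "BH"))
  out <- pvalues
  for (g in unique(grouping)) {
    i <- grouping == g
    out[i] <- stats::p.adjust(pvalues[i], method = "BH")
  }
  out
}

#' Compare two per-feature effect profiles
#'
#' Regresses the per-feature coefficients for term Y on those for term X
#' (least squares), and reports slope, intercept, r-squared, and the
#' fraction of features whose two coefficients have opposing signs
#' (computed over features significant for at least one term by default).
#'
#' @param results_x,results_y `association_result` tables (or data frames
#'   with `feature_id`, `beta`, `p_adj`), each filtered to a single
#'   contrast, or filtered here via `contrast_x`/`contrast_y`.
#' @param contrast_x,contrast_y Optional contrast names to select.
#' @param sig_scope `"either"` (default): opposing-sign fraction over
#'   features with `p_adj < alpha` for at least one term; `"all"`: over all
#'   shared features.
#' @param alpha Significance threshold for the scope filter.
#' @return An object of class `profile_comparison`: `slope`, `intercept`,
#'   `r_squared`, `opposing_fraction`, `n_shared`, `n_scope`, and the
#'   merged `data`.
#' @export
compare_effect_profiles <- function(results_x, results_y,
                                    contrast_x = NULL, contrast_y = NULL,
                                    sig_scope = c("either", "all"),
                                    alpha = 0.05) {
  sig_scope <- match.arg(sig_scope)
  pick <- function(r, ct) {
    if (!is.null(ct)) r <- r[r$contrast == ct, , drop = FALSE]
    if ("contrast" %in% names(r) && length(unique(r$contrast)) > 1L)
      stopf("compare_effect_profiles: results span multiple contrasts; select one")
    r
  }
  rx <- pick(as.data.frame(results_x), contrast_x)
  ry <- pick(as.data.frame(results_y), contrast_y)
  m <- merge(rx[, c("feature_id", "beta",
                    intersect("p_adj", names(rx)))],
             ry[, c("feature_id", "beta", intersect("p_adj", names(ry)))],
             by = "feature_id", suffixes = c("_x", "_y"))
  if (nrow(m) < 3L)
    stopf("compare_effect_profiles: need at least 3 shared features, got %d",
          nrow(m))
  fit <- stats::lm(beta_y ~ beta_x, data = m)
  r2 <- if (stats::sd(m$beta_y) == 0) 1 else stats::cor(m$beta_x, m$beta_y)^2
  scope <- if (sig_scope == "all" || !all(c("p_adj_x", "p_adj_y") %in% names(m)))
    rep(TRUE, nrow(m))
  else m$p_adj_x < alpha | m$p_adj_y < alpha
  opposing <- if (any(scope))
    mean(m$beta_x[scope] * m$beta_y[scope] < 0) else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 opposing_fraction = opposing,
                 n_shared = nrow(m), n_scope = sum(scope), data = m),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("Effect-profile comparison over %d shared features:\n", x$n_shared))
  cat(sprintf("  y = %.4fx + %.4f, r^2 = %.3f\n", x$slope, x$intercept,
              x$r_squared))
  cat(sprintf("  opposing-sign fraction: %.3f (over %d in scope)\n",
              x$opposing_fraction, x$n_scope))
  invisible(x)
}

# Forest-plot category layout: sphingolipids first, then phospholipids,
# then other lipids.
default_category_map <- function() {
  list(sphingolipids = c("SM", "Cer", "dhCer", "deoxyCer", "HexCer",
                         "Hex2Cer", "Hex3Cer", "GM3", "Sph", "S1P", "C1P"),
       phospholipids = c("PC", "PE", "PI", "PS", "PG", "LPC", "LPE", "LPI",
                         "PC(O)", "PC(P)", "PE(O)", "PE(P)"))
}

#' Export an ordered forest-plot table
#'
#' Orders one contrast's association results the way the forest plots are
#' laid out: category (sphingolipids, phospholipids, other lipids) then
#' lipid class then species, with a significance tier per row
#' (`"ns"`, `"significant"` for adjusted p < 0.05, `"top10"` for the 10
#' lowest p-values). Optional class-level results (fits of class totals)
#' are appended as `level = "class"` rows within each category.
#'
#' @param results `association_result` rows for a single contrast.
#' @param annotation Feature annotation; every result feature must appear.
#' @param class_results Optional class-total results (`feature_id` = class
#'   name).
#' @param top_n Number of lowest-p species to tier as top hits.
#' @param category_map Named list mapping category -> classes; classes not
#'   listed fall into `"other lipids"`.
#' @return Ordered data frame with annotation, estimates, CIs, percentage
#'   changes, p-values, `level`, `tier` and `tie_at_cutoff` columns.
#' @export
export_forest_table <- function(results, annotation, class_results = NULL,
                                top_n = 10L, category_map = default_category_map()) {
  results <- as.data.frame(results)
  if ("contrast" %in% names(results) && length(unique(results$contrast)) > 1L)
    stopf("export_forest_table: results span multiple contrasts; select one")
  unknown <- setdiff(results$feature_id, annotation$feature_id)
  if (length(unknown))
    stopf("export_forest_table: unannotated feature(s): %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
  tab <- merge(results, annotation[, c("feature_id", "class", "species")],
               by = "feature_id")
  cat_of <- function(cl) {
    for (cat in names(category_map)) if (cl %in% category_map[[cat]]) return(cat)
    "other lipids"
  }
  tab$category <- vapply(tab$class, cat_of, character(1))
  tab$level <- "species"

  ord <- order(tab$p, tab$feature_id)        # deterministic id tie-break
  tab$tier <- ifelse(tab$p_adj < 0.05, "significant", "ns")
  top <- utils::head(ord, top_n)
  tab$tier[top] <- "top10"
  tab$tie_at_cutoff <- FALSE
  if (nrow(tab) > top_n && tab$p[ord[top_n]] == tab$p[ord[top_n + 1L]])
    tab$tie_at_cutoff[tab$p == tab$p[ord[top_n]]] <- TRUE

  if (!is.null(class_results)) {
    cr <- as.data.frame(class_results)
    cr$class <- cr$feature_id
    cr$species <- NA_character_
    cr$category <- vapply(cr$class, cat_of, character(1))
    cr$level <- "class"
    cr$tier <- ifelse(cr$p_adj < 0.05, "significant", "ns")
    cr$tie_at_cutoff <- FALSE
    tab <- rbind(tab[, intersect(names(tab), names(cr))],
                 cr[, intersect(names(tab), names(cr))])
  }
  cats <- c(names(category_map), "other lipids")
  tab <- tab[order(match(tab$category, cats), tab$class,
                   tab$level == "class", tab$species), ]
  rownames(tab) <- NULL
  tab
}
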