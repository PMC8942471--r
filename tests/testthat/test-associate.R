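make_assoc_cohort <- function(n = 120, beta_ga = 0.001, noise = 0,
                              n_features = 3, seed = 51) {
  eff <- planted_effect(features = "F001", covariate = "gestational_age",
                        type = "slope", magnitude = beta_ga)
  cfg <- cohort_config(n_subjects = n, n_batches = 1, timepoints = "birth",
                       n_features = n_features, noise_sd = noise,
                       zero_rate = 0, missing_rate = 0, batch_shift_sd = 0,
                       batch_scale_sd = 0, effects = list(eff), seed = seed)
  generate_cohort(cfg)
}

test_that("a noiseless planted slope is recovered to machine precision", {
  coh <- make_assoc_cohort()
  bio <- coh$manifest$sample_id[coh$manifest$role == "biological"]
  fit <- fit_lipid_regressions(coh$matrix[bio, ], coh$covariates,
                               terms = c("gestational_age", "sex"))
  b <- fit[fit$feature_id == "F001" & fit$term == "gestational_age", ]
  expect_equal(b$beta, 0.001, tolerance = 1e-10)
  expect_lt(b$p, 1e-12)
  null <- fit[fit$feature_id == "F002" & fit$term == "gestational_age", ]
  expect_lt(abs(null$beta), 1e-12)
})

test_that("coefficients equal the closed-form normal-equations solution", {
  covs <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    x1 = c(1.2, 0.4, 3.3, 2.8, 0.9, 1.7, 2.2, 3.0),
    x2 = c(10, 12, 9, 14, 11, 13, 8, 15),
    x3 = c(0.1, 0.9, 0.5, 0.3, 0.8, 0.2, 0.7, 0.6))
  y <- c(5.1, 4.2, 7.9, 7.0, 4.8, 5.9, 6.6, 8.1)
  m <- tiny_matrix(cbind(10^y), ids = covs$sample_id, features = "F001")
  fit <- fit_lipid_regressions(m, covs, terms = c("x1", "x2", "x3"))
  X <- cbind(1, covs$x1, covs$x2, covs$x3)
  expected <- ols_normal_equations(X, y)
  expect_equal(fit$beta[match(c("x1", "x2", "x3"), fit$term)],
               unname(expected[2:4]), tolerance = 1e-9)

  # CIs match a per-feature stats::lm fit (reference implementation)
  lmfit <- lm(y ~ x1 + x2 + x3, data = covs)
  ci <- confint(lmfit)
  expect_equal(fit$ci_lo[fit$term == "x1"], ci["x1", 1], tolerance = 1e-9)
  expect_equal(fit$ci_hi[fit$term == "x3"], ci["x3", 2], tolerance = 1e-9)
  expect_equal(fit$p[fit$term == "x2"],
               summary(lmfit)$coefficients["x2", 4], tolerance = 1e-9)
})

test_that("listwise deletion records the effective n per fit", {
  coh <- make_assoc_cohort(n = 60, noise = 0.1)
  bio <- coh$manifest$sample_id[coh$manifest$role == "biological"]
  m <- coh$matrix[bio, ]
  m[1:5, "F002"] <- NA
  covs <- coh$covariates
  covs$gestational_age[match(bio[6], covs$sample_id)] <- NA
  fit <- fit_lipid_regressions(m, covs, terms = c("gestational_age", "sex"))
  expect_identical(unique(fit$n[fit$feature_id == "F001"]), 59L)
  expect_identical(unique(fit$n[fit$feature_id == "F002"]), 54L)
})

test_that("degenerate designs are rejected with the offending terms named", {
  coh <- make_assoc_cohort(n = 30, noise = 0.1)
  bio <- coh$manifest$sample_id[coh$manifest$role == "biological"]
  covs <- coh$covariates
  covs$dup <- covs$gestational_age * 2
  expect_error(
    fit_lipid_regressions(coh$matrix[bio, ], covs,
                          terms = c("gestational_age", "dup")),
    "collinear|rank")
  expect_error(
    fit_lipid_regressions(coh$matrix[bio[1:3], ], covs,
                          terms = c("gestational_age", "birth_weight",
                                    "maternal_bmi")),
    "parameters")
})

test_that("percentage change converts log10 coefficients as stated", {
  expect_identical(beta_to_percent_change(0), 0)
  expect_equal(beta_to_percent_change(1), 900)
  expect_equal(beta_to_percent_change(0.1), (exp(0.1 * log(10)) - 1) * 100,
               tolerance = 1e-12)
  expect_error(beta_to_percent_change(Inf), "finite")

  # strictly increasing; negated coefficient gives the reciprocal fold
  b <- seq(-2, 2, by = 0.25)
  pc <- beta_to_percent_change(b)
  expect_true(all(diff(pc) > 0))
  expect_equal((1 + pc / 100) * (1 + beta_to_percent_change(-b) / 100),
               rep(1, length(b)), tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(52)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), bh_reference(p), tolerance = 1e-12)
  }

  # grouping adjusts within term only
  p <- c(0.01, 0.04, 0.02, 0.5)
  g <- c("a", "a", "b", "b")
  expect_equal(bh_adjust(p, g), c(bh_reference(p[1:2]), bh_reference(p[3:4])))
})

test_that("permuted covariates give the nominal type-I error rate", {
  set.seed(53)
  n <- 200; nf <- 1000
  y <- matrix(10^rnorm(n * nf, 1, 0.2), n, nf,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("F%04d", 1:nf)))
  covs <- data.frame(sample_id = rownames(y), x = rnorm(n))
  fit <- fit_lipid_regressions(y, covs, terms = "x")
  expect_lt(abs(mean(fit$p < 0.05) - 0.05), 0.02)
})

test_that("effect-profile comparison recovers constructed relationships", {
  set.seed(54)
  bx <- rnorm(50)
  rx <- data.frame(feature_id = sprintf("F%02d", 1:50), beta = bx,
                   p_adj = rep(0.001, 50))
  ry <- transform(rx, beta = -2 * bx)
  cmp <- compare_effect_profiles(rx, ry)
  expect_equal(cmp$slope, -2, tolerance = 1e-12)
  expect_equal(cmp$r_squared, 1, tolerance = 1e-12)
  expect_equal(cmp$opposing_fraction, 1)

  # independent coefficients: no shared structure
  ry2 <- transform(rx, beta = rnorm(500)[1:50])
  rx2 <- data.frame(feature_id = sprintf("F%03d", 1:500), beta = rnorm(500),
                    p_adj = 0.001)
  ry3 <- transform(rx2, beta = rnorm(500))
  cmp2 <- compare_effect_profiles(rx2, ry3)
  expect_lt(cmp2$r_squared, 0.05)

  # closed-form slope and intercept on a 5-point toy
  x5 <- c(1, 2, 3, 4, 5); y5 <- c(2.2, 2.9, 4.1, 4.8, 6.3)
  r5x <- data.frame(feature_id = letters[1:5], beta = x5, p_adj = 0.01)
  r5y <- data.frame(feature_id = letters[1:5], beta = y5, p_adj = 0.01)
  cmp3 <- compare_effect_profiles(r5x, r5y)
  slope <- sum((x5 - mean(x5)) * (y5 - mean(y5))) / sum((x5 - mean(x5))^2)
  expect_equal(cmp3$slope, slope, tolerance = 1e-12)
  expect_equal(cmp3$intercept, mean(y5) - slope * mean(x5), tolerance = 1e-12)

  expect_error(compare_effect_profiles(r5x[1:2, ], r5y[1:2, ]), "at least 3")
})

test_that("adding an uncorrelated covariate barely moves the planted estimate", {
  coh <- make_assoc_cohort(n = 400, noise = 0.15, seed = 55)
  bio <- coh$manifest$sample_id[coh$manifest$role == "biological"]
  f1 <- fit_lipid_regressions(coh$matrix[bio, ], coh$covariates,
                              terms = "gestational_age")
  f2 <- fit_lipid_regressions(coh$matrix[bio, ], coh$covariates,
                              terms = c("gestational_age", "maternal_age"))
  b1 <- f1[f1$feature_id == "F001" & f1$term == "gestational_age", ]
  b2 <- f2[f2$feature_id == "F001" & f2$term == "gestational_age", ]
  expect_lt(abs(b1$beta - b2$beta), b1$se)
})

test_that("forest table is category-ordered with a deterministic top tier", {
  anno <- data.frame(
    feature_id = sprintf("F%02d", 1:12),
    class = rep(c("SM", "PC", "TG"), each = 4),
    species = sprintf("sp%02d", 1:12),
    mode = "standard", retained = TRUE, stringsAsFactors = FALSE)
  res <- data.frame(
    feature_id = anno$feature_id, term = "x", contrast = "x",
    beta = seq(-0.3, 0.3, length.out = 12), p = (1:12) / 100,
    p_adj = c(rep(0.01, 6), rep(0.2, 6)), n = 100)
  tab <- export_forest_table(res, anno, top_n = 3)
  expect_identical(nrow(tab), 12L)
  expect_identical(unique(tab$category),
                   c("sphingolipids", "phospholipids", "other lipids"))
  expect_identical(sum(tab$tier == "top10"), 3L)
  expect_identical(tab$feature_id[tab$tier == "top10"],
                   sprintf("F%02d", 1:3))

  # tie at the cutoff is flagged and broken by feature id
  res$p <- c(0.01, 0.02, 0.02, rep(0.5, 9))
  tab2 <- export_forest_table(res, anno, top_n = 2)
  expect_identical(sort(tab2$feature_id[tab2$tier == "top10"]),
                   c("F01", "F02"))
  expect_true(all(tab2$tie_at_cutoff[tab2$feature_id %in% c("F02", "F03")]))

  # class-level rows slot into their categories
  cls <- data.frame(feature_id = c("SM", "TG"), term = "x", contrast = "x",
                    beta = c(0.1, -0.1), p = c(0.001, 0.2),
                    p_adj = c(0.01, 0.4), n = 100)
  tab3 <- export_forest_table(res, anno, class_results = cls)
  expect_identical(sum(tab3$level == "class"), 2L)
  expect_identical(tab3$category[tab3$level == "class" & tab3$class == "SM"],
                   "sphingolipids")

  expect_error(export_forest_table(transform(res, feature_id = "zzz"), anno),
               "unannotated")
})
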