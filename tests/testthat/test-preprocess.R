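test_that("zeros are replaced by a tenth of the group minimum, per sample type", {
  m <- tiny_matrix(cbind(c(0, 2, 10, 0, 4, 8), c(1, 1, 1, 1, 1, 1)))
  man <- tiny_manifest(rownames(m),
                       timepoint = rep(c("birth", "6m"), each = 3))
  out <- replace_zeros(m, man)
  expect_equal(out[1, 1], 0.2)     # min positive in birth group is 2
  expect_equal(out[4, 1], 0.4)     # min positive in 6m group is 4
  expect_identical(out[, 2], m[, 2])           # no zeros: unchanged

  # positive-entry count preserved, group minima strictly increased
  expect_identical(sum(out > 0), sum(m > 0) + 2L)
  expect_gt(min(out[1:3, 1]), 0)

  all0 <- tiny_matrix(cbind(c(0, 0, 0)))
  man0 <- tiny_manifest(rownames(all0))
  expect_warning(res <- replace_zeros(all0, man0), "no positive minimum")
  expect_true(all(is.na(res[, 1])))
})

test_that("missing entries pass through zero replacement untouched", {
  m <- tiny_matrix(cbind(c(0, NA, 5, 50)))
  man <- tiny_manifest(rownames(m))
  out <- replace_zeros(m, man)
  expect_equal(out[1, 1], 0.5)
  expect_true(is.na(out[2, 1]))
})

test_that("PQC median centring equalizes batch PQC medians", {
  # batch B is batch A times a constant: the shift removes the offset
  set.seed(1)
  base <- matrix(10^runif(8 * 6, 0, 2), 8, 6)
  m <- rbind(base, base * 3)
  rownames(m) <- sprintf("s%02d", 1:16)
  colnames(m) <- sprintf("F%03d", 1:6)
  man <- tiny_manifest(rownames(m),
                       role = rep(rep(c("biological", "PQC"), c(5, 3)), 2),
                       batch = rep(c("A", "B"), each = 8))
  out <- harmonize_batches(m, man)
  L <- log10(out)
  pqcA <- apply(L[man$batch == "A" & man$role == "PQC", ], 2, median)
  pqcB <- apply(L[man$batch == "B" & man$role == "PQC", ], 2, median)
  expect_lt(max(abs(pqcA - pqcB)), 1e-9)
})

test_that("a single batch passes through harmonization unchanged", {
  set.seed(2)
  m <- tiny_matrix(matrix(10^runif(60, 0, 3), 10, 6))
  man <- tiny_manifest(rownames(m), role = rep(c("biological", "PQC"), c(7, 3)))
  out <- harmonize_batches(m, man)
  expect_equal(out, m, tolerance = 1e-12)
})

test_that("harmonization matches a step-by-step computation of its two formulas", {
  set.seed(3)
  m <- tiny_matrix(matrix(10^runif(2 * 9 * 5, 0, 2), 18, 5))
  man <- tiny_manifest(rownames(m),
                       role = rep(rep(c("biological", "PQC"), c(6, 3)), 2),
                       batch = rep(c("A", "B"), each = 9))
  out <- harmonize_batches(m, man)

  # independent, loop-based application of the two stated corrections
  L <- log10(m)
  for (j in seq_len(ncol(L))) {
    pqc_all <- L[man$role == "PQC", j]
    g <- median(pqc_all)
    for (b in c("A", "B")) {
      rows <- man$batch == b
      d <- median(L[rows & man$role == "PQC", j])
      L[rows, j] <- L[rows, j] + (g - d)
    }
    sds <- sapply(c("A", "B"), function(b)
      sd(L[man$batch == b & man$role == "biological", j]))
    target <- mean(sds)
    for (b in c("A", "B")) {
      rows <- man$batch == b
      ctr <- median(L[rows & man$role == "biological", j])
      L[rows, j] <- ctr + (L[rows, j] - ctr) * target / sds[[b]]
    }
  }
  expect_equal(out, 10^L, tolerance = 1e-12)
})

test_that("known batch shifts and scales are removed exactly on a balanced cohort", {
  fx <- replicated_batch_cohort()
  expect_false(isTRUE(all.equal(fx$perturbed, fx$clean, tolerance = 1e-4)))
  rec <- harmonize_batches(fx$perturbed, fx$manifest)
  rel <- abs(rec - fx$clean) / fx$clean
  expect_lt(max(rel), 1e-6)
})

test_that("harmonization is idempotent and preserves within-batch rank order", {
  fx <- replicated_batch_cohort(seed = 12)
  h1 <- harmonize_batches(fx$perturbed, fx$manifest)
  h2 <- harmonize_batches(h1, fx$manifest)
  expect_lt(max(abs(log10(h2) - log10(h1))), 1e-9)
  for (b in unique(fx$manifest$batch)) {
    rows <- fx$manifest$sample_id[fx$manifest$batch == b]
    for (j in c(1L, ncol(h1))) {
      expect_identical(order(h1[rows, j]), order(fx$perturbed[rows, j]))
    }
  }
})

test_that("harmonization refuses a batch without PQC anchors", {
  m <- tiny_matrix(matrix(1:12 + 0.5, 6, 2))
  man <- tiny_manifest(rownames(m),
                       role = c("biological", "biological", "PQC",
                                "biological", "biological", "biological"),
                       batch = rep(c("A", "B"), each = 3))
  expect_error(harmonize_batches(m, man), "fewer than 2 PQC")
})

test_that("kNN imputation uses the nearest neighbours in log10 sample space", {
  # a duplicate sample at distance zero donates its value at k = 1
  m <- tiny_matrix(rbind(c(1, 2, 4), c(1, 2, NA), c(100, 200, 400),
                         c(7, 9, 2)))
  man <- tiny_manifest(rownames(m))
  out <- impute_knn(m, man, k = 1)
  expect_equal(out["s02", "F003"], 4)
  expect_identical(out[!is.na(m)], m[!is.na(m)])

  # k = 2: hand-computed neighbour mean on enumerated distances
  m2 <- tiny_matrix(rbind(c(10, 10, NA), c(10, 20, 40), c(10, 11, 90),
                          c(1000, 1000, 7)))
  man2 <- tiny_manifest(rownames(m2))
  L <- log10(m2)
  d <- sapply(2:4, function(t) sqrt(sum((L[1, 1:2] - L[t, 1:2])^2)))
  nn <- order(d)[1:2] + 1L               # two closest donors: s03, s02
  expected <- 10^mean(L[nn, 3])
  expect_equal(impute_knn(m2, man2, k = 2)["s01", "F003"], expected)
})

test_that("imputation is an identity on complete data and respects groups", {
  set.seed(4)
  m <- tiny_matrix(matrix(10^runif(40, 0, 2), 8, 5))
  man <- tiny_manifest(rownames(m))
  expect_identical(impute_knn(m, man, k = 3), m)

  # imputed values stay inside the observed range of the feature's group
  m[2, 3] <- NA; m[5, 1] <- NA
  out <- impute_knn(m, man, k = 3)
  expect_true(out[2, 3] >= min(m[, 3], na.rm = TRUE) &&
                out[2, 3] <= max(m[, 3], na.rm = TRUE))

  allmiss <- m; allmiss[, 2] <- NA
  expect_error(impute_knn(allmiss, man, k = 2), "F002")
})

test_that("identical samples yield no declared outliers under strict thresholds", {
  m <- tiny_matrix(matrix(rep(10^runif(8, 0, 2), each = 20), 20, 8))
  man <- tiny_manifest(rownames(m))
  rep_ <- detect_outliers(m, man, n_components = 5)
  expect_identical(rep_$declared, character(0))
  expect_true(all(rep_$pc_distance < 1e-8))
})

test_that("a grossly scaled sample is the only declared outlier", {
  cfg <- cohort_config(n_subjects = 12, n_batches = 1, n_features = 10,
                       noise_sd = 0, zero_rate = 0, missing_rate = 0,
                       batch_shift_sd = 0, batch_scale_sd = 0,
                       qc_noise_sd = 0, seed = 6)
  coh <- generate_cohort(cfg)
  oo <- inject_outliers(coh$matrix, coh$manifest, n = 1, scale = 100, seed = 2)
  rep_ <- detect_outliers(oo$matrix, coh$manifest)
  expect_identical(rep_$declared, oo$sample_ids)
  expect_true(all(rep_$declared %in% rep_$flagged_zsum))
  expect_true(all(rep_$declared %in% rep_$flagged_pc))

  # intermediates agree with a brute-force recomputation through eigen()
  bio <- coh$manifest$sample_id[coh$manifest$role == "biological"]
  X <- log10(oo$matrix[bio, ])
  Z <- X
  for (j in seq_len(ncol(X))) Z[, j] <- (X[, j] - mean(X[, j])) / sd(X[, j])
  expect_equal(rep_$sum_abs_z[bio], rowSums(abs(Z))[bio], tolerance = 1e-9)
  ev <- eigen(t(Z) %*% Z, symmetric = TRUE)$vectors[, 1:7]
  expect_equal(unname(rep_$pc_distance[bio]),
               unname(sqrt(rowSums((Z %*% ev)^2))), tolerance = 1e-8)
})

test_that("a sample extreme in summed |Z| but not in PC space is not declared", {
  # cohort variation confined to 7 orthogonal patterns; the crafted sample
  # has a damped pattern component (small distance in the retained PC
  # space) plus a large deviation along an orthogonal direction, which
  # inflates its summed |Z| without loading the leading components
  set.seed(7)
  n <- 120; p <- 200
  Q <- qr.Q(qr(matrix(rnorm(p * 8), p, 8)))
  C <- matrix(rnorm(n * 7), n, 7)
  C[1, ] <- C[1, ] * 0.2
  L <- 1 + 0.1 * C %*% t(Q[, 1:7])
  L[1, ] <- L[1, ] + 0.5 * Q[, 8]
  m <- 10^L
  dimnames(m) <- list(sprintf("s%03d", 1:n), sprintf("F%03d", 1:p))
  man <- tiny_manifest(rownames(m))
  rep_ <- detect_outliers(m, man)
  expect_true("s001" %in% rep_$flagged_zsum)
  expect_false("s001" %in% rep_$flagged_pc)
  expect_false("s001" %in% rep_$declared)
})

test_that("exclusion bookkeeping matches the cohort's printed retention", {
  man <- tiny_manifest(sprintf("s%04d", 1:4007))
  man$exclusion[1:16] <- "missed_injection"
  man$exclusion[17:43] <- "maternal_contamination"
  res <- apply_exclusions(man, character(0))
  s <- res$summary
  expect_identical(s$n[s$reason == "retained"], 3964L)
  expect_identical(s$n[s$reason == "total"], 4007L)

  # no flags at all: everything retained
  clean <- apply_exclusions(tiny_manifest(sprintf("s%d", 1:10)), character(0))
  expect_identical(clean$summary$n[clean$summary$reason == "retained"], 10L)

  # a sample both contaminated and outlier is counted once
  man2 <- tiny_manifest(sprintf("s%d", 1:10))
  man2$exclusion[1] <- "maternal_contamination"
  res2 <- apply_exclusions(man2, c("s1", "s2"))
  expect_identical(res2$summary$n[res2$summary$reason == "retained"], 8L)
  expect_identical(res2$manifest$exclusion[1], "maternal_contamination")

  expect_error(apply_exclusions(man2, "nope"), "unknown sample id")
})

test_that("feature retention and the species-level view count correctly", {
  anno <- data.frame(
    feature_id = sprintf("F%03d", 1:777),
    class = "PC", species = sprintf("sp%d", 1:777),
    mode = c(rep("SIM", 43), rep("standard", 734)),
    retained = TRUE, stringsAsFactors = FALSE)
  res <- retain_features(anno, "F777")
  expect_identical(res$n_retained, 776L)
  expect_identical(res$n_species, 733L)

  res0 <- retain_features(anno)
  expect_identical(res0$n_retained, 777L)

  small <- anno[1:10, ]; small$mode <- c(rep("SIM", 3), rep("standard", 7))
  expect_identical(retain_features(small)$n_species, 7L)
  expect_error(retain_features(anno, "Fxxx"), "unknown feature")
})

test_that("class totals sum species, with SIM-only summation for TG classes", {
  m <- tiny_matrix(rbind(c(1, 2, 3, 5, 5, 4, 6)),
                   features = sprintf("F%d", 1:7))
  anno <- data.frame(
    feature_id = sprintf("F%d", 1:7),
    class = c("PC", "PC", "PC", "TG", "TG", "TG", "TG"),
    species = sprintf("sp%d", 1:7),
    mode = c("standard", "standard", "standard", "NL", "NL", "SIM", "SIM"),
    retained = TRUE, stringsAsFactors = FALSE)
  tot <- compute_class_totals(m, anno)
  expect_equal(unname(tot[1, "PC"]), 6)
  expect_equal(unname(tot[1, "TG"]), 10)    # SIM-only: 4 + 6

  expect_error(
    compute_class_totals(m, transform(anno, mode = "SIM")),
    "class 'PC'")

  # random fixture against an independent group-by-sum oracle
  set.seed(8)
  cfg <- cohort_config(n_subjects = 6, n_batches = 1, n_features = 36,
                       zero_rate = 0, missing_rate = 0, seed = 13)
  coh <- generate_cohort(cfg)
  tot2 <- compute_class_totals(coh$matrix, coh$annotation)
  for (cl in colnames(tot2)) {
    use <- if (cl %in% c("TG", "TG(O)")) "SIM" else c("standard", "NL")
    ids <- coh$annotation$feature_id[coh$annotation$class == cl &
                                       coh$annotation$mode %in% use]
    expect_equal(tot2[, cl],
                 apply(coh$matrix[, ids, drop = FALSE], 1, sum))
  }
})
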