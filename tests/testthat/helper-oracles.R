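# Independent oracles used to check package computations. These are
# deliberately naive (enumeration / closed form) and share no code with
# the implementation.

# DTW by brute-force enumeration of all admissible warping paths.
dtw_brute <- function(a, b) {
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return()
    if (i == length(a) && j == length(b)) {
      best <<- acc
      return()
    }
    if (i < length(a)) recurse(i + 1L, j, acc)
    if (j < length(b)) recurse(i, j + 1L, acc)
    if (i < length(a) && j < length(b)) recurse(i + 1L, j + 1L, acc)
  }
  recurse(1L, 1L, 0)
  best
}

# Exhaustive k-medoid optimum over all medoid subsets.
pam_brute <- function(D, k) {
  combos <- utils::combn(nrow(D), k)
  costs <- apply(combos, 2L, function(m)
    sum(apply(D[, m, drop = FALSE], 1L, min)))
  list(cost = min(costs),
       medoids = sort(combos[, which.min(costs)]))
}

# Exact two-sided Wilcoxon signed-rank p-value by enumeration over all
# 2^n sign assignments (no ties, no zeros).
wilcoxon_enum_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  stats <- apply(as.matrix(signs), 1L, function(s) sum(r[s]))
  p_le <- mean(stats <= t_obs)
  p_ge <- mean(stats >= t_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg step-up reference: p_(i) * m / i with monotone
# enforcement from the largest rank down, capped at 1.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(1, adj)[order(o)]
}

# Closed-form OLS via the normal equations.
ols_normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Small cohort fixtures -------------------------------------------------

tiny_manifest <- function(ids, role = "biological", batch = "B1",
                          timepoint = "6m", matrix = "plasma",
                          exclusion = "none") {
  data.frame(sample_id = ids, subject_id = ids, role = role, batch = batch,
             timepoint = timepoint, matrix = matrix, exclusion = exclusion,
             stringsAsFactors = FALSE)
}

tiny_matrix <- function(values, ids = NULL, features = NULL) {
  m <- as.matrix(values)
  rownames(m) <- ids %||% sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- features %||% sprintf("F%03d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A 3-batch cohort whose batches are exact replicas of one generated batch,
# perturbed with known, invertible shift/scale batch effects: the balanced
# construction under which harmonization recovers the clean matrix exactly.
replicated_batch_cohort <- function(n_subjects = 30, n_features = 12,
                                    shifts = c(B01 = -0.2, B02 = 0, B03 = 0.3),
                                    scales = c(B01 = 0.8, B02 = 1.0, B03 = 1.2),
                                    seed = 11) {
  stopifnot(abs(mean(scales) - 1) < 1e-12, median(shifts) == 0)
  cfg <- cohort_config(n_subjects = n_subjects, n_batches = 1L,
                       n_features = n_features, zero_rate = 0,
                       missing_rate = 0, batch_shift_sd = 0,
                       batch_scale_sd = 0, qc_noise_sd = 0, seed = seed)
  coh <- generate_cohort(cfg)
  mats <- list(); mans <- list()
  for (b in names(shifts)) {
    m <- coh$matrix
    rownames(m) <- paste(b, rownames(m), sep = "_")
    man <- coh$manifest
    man$sample_id <- paste(b, man$sample_id, sep = "_")
    man$batch <- b
    mats[[b]] <- m; mans[[b]] <- man
  }
  clean <- do.call(rbind, mats)
  manifest <- do.call(rbind, mans)
  shift_mat <- matrix(rep(shifts, n_features), length(shifts), n_features,
                      dimnames = list(names(shifts),
                                      colnames(clean)))
  perturbed <- inject_batch_effects(clean, manifest, shift_mat, scales)
  list(clean = clean, perturbed = perturbed, manifest = manifest)
}
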