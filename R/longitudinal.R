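# Paired between-group/between-timepoint comparisons and trajectory
# clustering by dynamic time warping + partitioning around medoids.

#' Paired per-feature comparisons
#'
#' For each feature, compares paired samples (e.g. mother vs cord serum, or
#' the same infant at two time points) with a paired Wilcoxon signed-rank
#' test (exact when n <= 25 and no zero/tied differences, otherwise normal
#' approximation with continuity correction) or a paired t-test on log10
#' differences. Summaries: geometric fold difference side1/side2
#' `10^mean(paired log10 difference)` and `log2FC = mean(paired log2
#' difference)`; BH adjustment across features.
#'
#' @param matrix Samples x features concentration matrix, zeros replaced.
#' @param pairing Data frame with columns `sample_1` and `sample_2`, one
#'   row per pair; only complete pairs (both samples present, both values
#'   observed) enter each feature's test.
#' @param test `"wilcoxon"` or `"ttest"`.
#' @return Data frame of class `paired_comparison`: `feature_id`,
#'   `n_pairs`, `fold`, `log2fc`, `p`, `p_adj`, `test`, `degenerate` (all
#'   differences zero under Wilcoxon).
#' @export
paired_compare <- function(matrix, pairing, test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  check_matrix(matrix)
  if (!all(c("sample_1", "sample_2") %in% names(pairing)))
    stopf("paired_compare: pairing needs 'sample_1' and 'sample_2' columns")
  ok <- pairing$sample_1 %in% rownames(matrix) &
    pairing$sample_2 %in% rownames(matrix)
  pairing <- pairing[ok, , drop = FALSE]
  if (!nrow(pairing)) stopf("paired_compare: zero complete pairs")
  L <- safe_log10(matrix, "paired_compare")
  A <- L[pairing$sample_1, , drop = FALSE]
  B <- L[pairing$sample_2, , drop = FALSE]
  res <- lapply(seq_len(ncol(L)), function(j) {
    d <- A[, j] - B[, j]
    d <- d[!is.na(d)]
    n <- length(d)
    if (!n)
      return(data.frame(feature_id = colnames(L)[j], n_pairs = 0L,
                        fold = NA_real_, log2fc = NA_real_, p = NA_real_,
                        test = test, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    fold <- 10^mean(d)
    log2fc <- mean(d) / log10(2)
    degen <- FALSE
    if (test == "wilcoxon") {
      if (all(d == 0)) {
        p <- 1; degen <- TRUE
      } else {
        nz <- d[d != 0]
        exact <- n <= 25L && !any(d == 0) && !anyDuplicated(abs(nz))
        p <- suppressWarnings(
          stats::wilcox.test(d, exact = exact, correct = TRUE)$p.value)
      }
    } else {
      if (stats::sd(d) == 0) {
        # constant differences: t statistic undefined at 0, certain otherwise
        p <- if (all(d == 0)) 1 else 0
        degen <- all(d == 0)
      } else p <- stats::t.test(d)$p.value
    }
    data.frame(feature_id = colnames(L)[j], n_pairs = n, fold = fold,
               log2fc = log2fc, p = p, test = test, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (all(is.na(out$p))) stopf("paired_compare: zero complete pairs")
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  out <- out[, c("feature_id", "n_pairs", "fold", "log2fc", "p", "p_adj",
                 "test", "degenerate")]
  class(out) <- c("paired_comparison", "data.frame")
  out
}

#' Dynamic time warping distance
#'
#' Classic DTW between two ordered series: absolute-difference local cost,
#' symmetric unit steps (match, insert, delete), no warping window. Returns
#' the optimal cumulative path cost.
#'
#' @param a,b Finite numeric vectors, length >= 1.
#' @return Non-negative dissimilarity.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 2, 3))   # 0
#' dtw_distance(c(0, 0), c(1, 1))            # 2
#' @export
dtw_distance <- function(a, b) {
  if (!length(a) || !length(b))
    stopf("dtw_distance: trajectories must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stopf("dtw_distance: trajectories must be finite")
  n <- length(a); m <- length(b)
  prev <- c(0, rep(Inf, m))
  for (i in seq_len(n)) {
    cur <- rep(Inf, m + 1L)
    for (j in seq_len(m)) {
      cost <- abs(a[i] - b[j])
      cur[j + 1L] <- cost + min(prev[j], prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Pairwise DTW dissimilarity matrix
#'
#' @param trajectories Numeric matrix, one series per row.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
dtw_matrix <- function(trajectories) {
  n <- nrow(trajectories)
  D <- matrix(0, n, n, dimnames = list(rownames(trajectories),
                                       rownames(trajectories)))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- dtw_distance(trajectories[i, ], trajectories[j, ])
  D
}

pam_total_cost <- function(D, medoids) {
  sum(do.call(pmin, lapply(medoids, function(m) D[, m])))
}

pam_swap <- function(D, medoids) {
  n <- nrow(D)
  repeat {
    cost <- pam_total_cost(D, medoids)
    best <- NULL; best_cost <- cost
    for (mi in seq_along(medoids)) {
      for (h in setdiff(seq_len(n), medoids)) {
        cand <- medoids; cand[mi] <- h
        cc <- pam_total_cost(D, cand)
        if (cc < best_cost - 1e-12) { best_cost <- cc; best <- cand }
      }
    }
    if (is.null(best)) return(medoids)
    medoids <- sort(best)
  }
}

pam_build <- function(D, k) {
  n <- nrow(D)
  medoids <- unname(which.min(colSums(D)))[1L]
  while (length(medoids) < k) {
    cur <- do.call(pmin, lapply(medoids, function(m) D[, m]))
    gain <- vapply(seq_len(n), function(h) {
      if (h %in% medoids) return(-Inf)
      sum(pmax(cur - D[, h], 0))
    }, numeric(1))
    medoids <- c(medoids, unname(which.max(gain))[1L])
  }
  sort(medoids)
}

#' Partitioning around medoids on a precomputed dissimilarity matrix
#'
#' BUILD initialization followed by SWAP refinement (best improving swap
#' until none remains), repeated from `restarts - 1` additional random
#' initializations; the solution with the lowest total within-cluster
#' dissimilarity wins (ties: the earliest). Fully deterministic given
#' `seed`.
#'
#' @param dmatrix Square symmetric non-negative dissimilarity matrix with
#'   zero diagonal.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer seed for the random restarts.
#' @param restarts Total number of initializations (>= 1; the first is
#'   BUILD).
#' @return List of class `pam_result`: `medoids` (indices), `medoid_ids`,
#'   `clustering` (cluster index per point, named), `cost`, `k`.
#' @export
pam_cluster <- function(dmatrix, k, seed = 1L, restarts = 10L) {
  if (!is.matrix(dmatrix) || nrow(dmatrix) != ncol(dmatrix))
    stopf("pam_cluster: 'dmatrix' must be square")
  if (any(dmatrix < 0) || any(abs(dmatrix - t(dmatrix)) > 1e-8) ||
      any(diag(dmatrix) != 0))
    stopf("pam_cluster: 'dmatrix' must be symmetric, non-negative, zero-diagonal")
  n <- nrow(dmatrix)
  if (k < 1L || k > n) stopf("pam_cluster: k must lie in [1, %d]", n)
  starts <- c(list(pam_build(dmatrix, k)),
              if (restarts > 1L) with_seed(seed, lapply(
                seq_len(restarts - 1L), function(i) sort(sample(n, k)))))
  best <- NULL; best_cost <- Inf
  for (s in starts) {
    med <- pam_swap(dmatrix, s)
    cc <- pam_total_cost(dmatrix, med)
    if (cc < best_cost - 1e-12) { best_cost <- cc; best <- med }
  }
  assign_to <- apply(dmatrix[, best, drop = FALSE], 1L, which.min)
  ids <- rownames(dmatrix) %||% as.character(seq_len(n))
  clustering <- stats::setNames(as.integer(assign_to), ids)
  structure(list(medoids = best, medoid_ids = ids[best],
                 clustering = clustering, cost = best_cost, k = k),
            class = "pam_result")
}

#' Cluster per-feature time trajectories
#'
#' Builds one trajectory per lipid feature — the median (or mean) log10
#' concentration of biological samples at each time point, z-normalized per
#' feature so clustering captures trajectory shape rather than abundance —
#' then computes pairwise DTW dissimilarities and partitions the features
#' around `k` medoids.
#'
#' @param matrix Samples x features concentration matrix, zeros replaced.
#' @param manifest Sample manifest; non-excluded biological samples are
#'   used, time points in order of first appearance.
#' @param k Number of clusters (default 10).
#' @param seed Integer seed for PAM restarts.
#' @param restarts PAM restarts (default 10).
#' @param center `"median"` (default) or `"mean"` per time point.
#' @param normalize Z-normalize each trajectory (default `TRUE`).
#' @return Object of class `trajectory_clustering`: `trajectories`
#'   (features x timepoints), `dmatrix`, `k`, `medoid_ids`, `assignments`
#'   (named integer vector), `sizes`, `medoid_trajectories`, `cost`.
#' @export
cluster_trajectories <- function(matrix, manifest, k = 10L, seed = 1L,
                                 restarts = 10L, center = c("median", "mean"),
                                 normalize = TRUE) {
  center <- match.arg(center)
  check_matrix(matrix)
  manifest <- check_manifest(manifest, rownames(matrix))
  manifest <- manifest[match(rownames(matrix), manifest$sample_id), ]
  bio <- manifest$role == "biological" & manifest$exclusion == "none"
  tps <- unique(manifest$timepoint[bio])
  if (length(tps) < 2L)
    stopf("cluster_trajectories: need biological samples at >= 2 time points")
  if (ncol(matrix) < k)
    stopf("cluster_trajectories: fewer features (%d) than clusters (%d)",
          ncol(matrix), k)
  L <- safe_log10(matrix, "cluster_trajectories")
  fun <- if (center == "median") stats::median else mean
  traj <- vapply(tps, function(tp) {
    rows <- bio & manifest$timepoint == tp
    apply(L[rows, , drop = FALSE], 2L, fun, na.rm = TRUE)
  }, numeric(ncol(L)))
  dimnames(traj) <- list(colnames(L), tps)
  if (normalize) {
    mu <- rowMeans(traj)
    sdv <- apply(traj, 1L, stats::sd)
    traj <- sweep(traj, 1L, mu)
    traj <- sweep(traj, 1L, ifelse(sdv > 0, sdv, 1), `/`)
  }
  D <- dtw_matrix(traj)
  pam <- pam_cluster(D, k, seed = seed, restarts = restarts)
  structure(list(trajectories = traj, dmatrix = D, k = k,
                 medoid_ids = pam$medoid_ids,
                 assignments = pam$clustering,
                 sizes = as.integer(table(pam$clustering)),
                 medoid_trajectories = traj[pam$medoid_ids, , drop = FALSE],
                 cost = pam$cost),
            class = "trajectory_clustering")
}

#' @export
print.trajectory_clustering <- function(x, ...) {
  cat(sprintf("Trajectory clustering: %d features, %d time points, k = %d\n",
              nrow(x$trajectories), ncol(x$trajectories), x$k))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("medoids:", paste(x$medoid_ids, collapse = ", "), "\n")
  invisible(x)
}
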