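---
title: "Methods: QC-anchored harmonization and association analysis for cohort lipidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC-anchored harmonization and association analysis for cohort lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidcohort)
```

This vignette documents the statistical procedures implemented in
`lipidcohort`, the assumptions behind them, the tunable parameters, and
the design decisions taken where the methodology was genuinely open.

## Data model

A cohort is a triple of plain tables: a **concentration matrix** (samples
× lipid features, arbitrary units relative to internal standards, `0` =
below detection, `NA` = missing), a **sample manifest** (role:
biological / PQC / TQC / NIST; batch; time point; subject; matrix:
serum / plasma; exclusion flag) and a **feature annotation** (lipid
class, species, quantification mode: standard / NL / SIM). All
statistical work happens on the log10 scale; "log" means log10
throughout, including the "log scale" of the batch-alignment step, so a
regression coefficient β converts to a percentage difference as
$(10^{\beta}-1)\times 100$.

"Sample types" — the grouping used for zero replacement and imputation —
are time point × matrix for biological samples, while each QC role forms
its own group: a detection-limit proxy or an imputation donor should
never cross from pooled QC material into biological samples, nor from
serum into plasma.

## Preprocessing chain

The chain runs in a fixed order: zeros → batch alignment → imputation →
outlier detection → exclusions. Each step assumes the previous one.

**Zero replacement.** A zero for lipid $f$ in sample-type group $g$
becomes $\min^{+}_{g}(f)/10$, a tenth of the smallest positive observed
value of that lipid in the group. If a lipid has no positive value in a
group there is no minimum to divide, and its zeros become missing with a
warning, to be handled by imputation or feature retention.

**Batch harmonization.** Pooled plasma QC (PQC) samples are aliquots of
one pool injected every 20 samples, so their expected value is constant
across batches; any displacement of a batch's PQC median is a batch
location effect. Per lipid, on log10: (1) every sample in batch $b$ is
shifted by (global PQC median − batch-$b$ PQC median); (2) each batch is
rescaled about its biological-sample median so the batch SD of biological
samples equals the across-batch mean of those SDs. The SD is estimated
from biological samples only (the QC replicate spread reflects technical
noise, not cohort variance), but the affine correction is applied to all
samples of the batch so QC samples stay on the same scale as the cohort
they anchor. Two open choices are documented as arguments: the mean of
batch SDs is unweighted by default (`sd_weighting = "weighted"` weights
by biological sample count), and a lipid whose batch SD is zero is left
unscaled in that batch.

Both corrections are affine with positive slope, so within-batch rank
order per lipid is preserved, and the map is idempotent. Exact recovery
of a known perturbation is only algebraically possible when the batches
are exchangeable — identical biological value multisets, a QC pool equal
to the per-lipid biological median, scale factors averaging 1 and shifts
with median 0; the test suite constructs exactly this balanced fixture
and verifies recovery to below 1e-6 relative error. On randomly composed
batches the rescale-to-mean-SD step necessarily mixes batch composition
differences into the correction, which is the expected behaviour, not a
defect.

**kNN imputation.** A missing value $(s, f)$ is the back-transformed mean
log10 value of $f$ over the $k$ nearest samples of the same sample type,
with distance the unnormalized Euclidean distance over jointly observed
log10 features, eligibility restricted to samples with $f$ observed, and
ties broken by sample id lexicographic order. The default $k = 5$ is the
usual compromise between noise averaging and locality for cohort-scale
groups (tens to hundreds of samples); the method assumes missingness is
unrelated to the missing value itself, which is reasonable for injection
failures but not for censoring (censoring is handled separately as
zeros).

**Dual-criterion outlier detection.** Biological samples are scored two
ways on per-lipid Z-scores of log10 values: the summed absolute Z-score
(criterion A, sensitive to diffuse extremeness) and the Euclidean
distance to the origin in the space of the first 7 principal-component
scores of the Z matrix (criterion B, sensitive to extremeness along the
dominant covariance directions). The PCA is computed on the already
unit-variance Z matrix with no second centring or scaling, and scores are
not eigenvalue-weighted. Each criterion flags samples above its 95th
percentile; only samples flagged by **both** are declared outliers,
trading sensitivity for a low false-declaration rate. Percentiles use
linear interpolation between order statistics (R quantile type 7) and
flagging is strict (`>`), so in a degenerate cohort where all samples tie
at the threshold nothing is declared. Both the number of components
(default 7) and the percentile (default 0.95) are arguments; percentiles
are computed globally, not within time point. QC samples are monitored
but never declared cohort outliers.

**Retention bookkeeping.** Pre-set exclusion flags (missed injections,
maternal contamination of cord serum) take precedence over the outlier
flag, and a sample excluded for several reasons is counted once. The
species-level feature view drops SIM-mode measures, which duplicate
neutral-loss measures of the same species with less structural
resolution; class totals conversely use **only** SIM measures for the TG
and TG(O) classes (abundant and quantitatively more reliable there) and
non-SIM measures everywhere else.

## Quality metrics

The per-lipid coefficient of variation from PQC replicates is
$100 \cdot s/\bar{x}$ on the concentration scale with the $n-1$ sample
SD — the convention behind the field's "CV < 20%" acceptance threshold.
CV is computed after harmonization by default (it then measures the
precision an analyst actually works with); passing the raw matrix gives
the pre-alignment value.

## Association engine

One ordinary-least-squares fit of log10 concentration per lipid, with
listwise deletion per fit and the effective n recorded. Confidence
intervals are t-based; percentage changes are the elementwise transform
of the estimate and both CI bounds. P-values are BH-adjusted per design
contrast across lipids, never across terms, so each term controls its own
false-discovery rate. Categorical covariates use treatment coding with
documented references: unassisted vaginal birth for mode of birth, female
for sex, "n" for yes/no covariates. Covariate presets name the standard
models: `birth` (gestational age, birth weight, mode of birth, duration
of labour, sex, maternal BMI, GDM, maternal education, maternal age,
birth order, run batch) and the breastfeeding models, which adjust for
child age and sex plus the maternal covariates; gestational age enters
at 6 months only, since its influence on the infant lipidome has faded by
12 months. Run batch is kept in the breastfeeding models for symmetry
with the birth model; both choices are arguments, not constants. A
rank-deficient design or a constant factor is an error naming the terms
rather than a silent drop.

Degenerate fits deserve a note: with zero residual variance the t
statistic of a truly null term is 0/0, and the engine reports `NA`
p-values for such lipids rather than inventing one; adjusted p-values
are computed over the non-missing set.

## Paired comparisons and trajectory clustering

Paired tests operate on within-pair log10 differences. The Wilcoxon
signed-rank test is exact for n ≤ 25 when no zero or tied absolute
differences occur, otherwise the normal approximation with continuity
correction is used; all-zero differences return p = 1 with a degenerate
flag. The fold difference is geometric — $10^{\overline{\Delta
\log_{10}}}$ — rather than a ratio of medians, so that
$\log_{10}(\text{fold}) / \log_{10} 2 = \text{log2FC}$ holds exactly and
fold differences compose across comparisons; this aggregation choice is
recorded here because "fold difference" alone does not pin it down.

Trajectories are summarized per lipid as the median log10 concentration
per time point over non-excluded biological samples, then z-normalized
per lipid. Normalization matters: dynamic time warping on raw
concentrations would cluster lipids by abundance (which spans four orders
of magnitude) instead of by trajectory shape. Both the centring statistic
(`median`/`mean`) and the normalization are arguments. DTW uses the
classic symmetric unit-step pattern with absolute-difference local cost
and no warping window; partitioning around medoids runs BUILD followed by
best-improving SWAP, repeated from 9 additional random seeded
initializations (10 total), keeping the lowest total within-cluster
dissimilarity, with k = 10 clusters by default and no automatic k
selection. All time points with biological samples enter each lipid's
trajectory. Determinism is part of the contract: a seed fixes the
restarts, distance ties in assignment go to the lowest medoid index, and
equal-cost restarts keep the earliest solution.

## Synthetic cohort generator

`generate_cohort()` emulates the statistical structure the downstream
chain assumes, not the instrument: per-lipid log10-normal baselines with
means drawn uniformly on [−1, 3] (four orders of magnitude, stressing
log-scale processing), per-lipid residual SDs drawn from [0.10, 0.20]
log10 units (roughly 25–60% biological CV), per-lipid random-walk age
trajectories (step SD 0.15 log10) unless explicit `time_profiles` are
planted, and planted covariate effects as log10 slopes or group fold
differences. Gestational age (days) and birth weight (kg) are drawn
jointly with correlation 0.45, and mode of birth uses the four-level
proportions 525:214:178:155 typical of an Australian birth cohort.
Batches hold one pooled QC and one technical QC per 20 biological
samples and one reference sample per 40, with a floor of two PQCs per
batch (the harmonizer's precondition). The QC pool profile is the
per-lipid median of the generated biological samples — a pooled QC *is*
pooled study material — and PQC replicate SDs are drawn log-normally
around 0.044 log10 units (≈10% CV, with roughly 93% of lipids below 20%
CV), matching routine targeted-lipidomics precision.

Batch perturbations are additive shifts plus multiplicative scales on
log10, applied about each batch's biological median — exactly the
structure the harmonizer removes. Drawn shifts are median-centred across
batches per lipid and scale factors normalized to mean 1: an
identifiability convention (the overall location/scale of a lipid is not
a batch property) that also makes exact-recovery tests well-posed. Zeros
are genuine censoring — each lipid's detection threshold sits at the
configured quantile of its concentration distribution — while
missingness is independent of value, mirroring the two distinct
mechanisms the preprocessing chain assumes.

What the generator does **not** emulate: within-batch drift, lipid
hydrolysis over run time, retention-time artefacts, correlated
missingness, non-affine batch distortions, realistic lipid-lipid
correlation structure, or cohort attrition (every subject is sampled at
every time point). Tests passing on these cohorts therefore demonstrate
the correctness of the computations and their behaviour under the stated
generative assumptions, not robustness to every failure mode of real
LC-MS data.

## Numerical conventions

- Quantiles: type 7 (linear interpolation); flagging strict `>`.
- Ties: sample id lexicographic order (imputation donors, top-10 ranks),
  lowest index (PAM assignment), earliest solution (equal-cost restarts).
- Logarithms base 10 everywhere; log2 only in reported log2FC.
- Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; the same seed reproduces outputs bit-identically.

## Verification scale

The test suite and `scripts/acceptance.R` exercise the chain at sizes
chosen to make the statistical checks sharp yet quick: CI coverage and
type-I error over 200 replicated cohorts of 800 subjects × 50 lipids
(10,000 intervals); the outlier rule on 500-sample cohorts with 5
injected ×100 outliers; the planted 17-fold breastfeeding recovery at
700 subjects; trajectory clustering on 10 planted archetypes × 20 lipids;
DTW and PAM against exhaustive enumeration for series of length ≤ 6 and
instances of n ≤ 10; Wilcoxon p-values against full 2^n sign-flip
enumeration for n ≤ 10. The pooled-QC precision summary uses a
default-configuration cohort of 150 subjects across 11 batches.

## Known limitations

- The harmonizer assumes batch effects are affine on log10 and that PQCs
  are exchangeable across batches; drift within a batch is out of scope.
- kNN imputation is O(n²) per sample-type group; adequate for cohort
  group sizes (≤ a few thousand), not for single-cell-scale data.
- PAM recomputes the objective per candidate swap; fine for a few hundred
  features, and the exhaustive tests bound its optimality gap only at
  small n — at larger n the restarts are the safeguard.
- Exact Wilcoxon p-values are used only for n ≤ 25 without ties; beyond
  that the continuity-corrected normal approximation applies.
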