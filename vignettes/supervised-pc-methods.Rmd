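---
title: "Supervised principal components for clinical association: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised principal components for clinical association: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superpca)
```

## The problem

Expression studies routinely face a matrix with thousands of features and at
most a few hundred patients, plus one clinical outcome per patient: a
possibly censored survival time, a continuous measurement, or a binary state
such as responder versus non-responder. Unsupervised PCA compresses the
matrix along its largest variance directions, but nothing guarantees those
directions track the outcome. Supervised PCA screens features by their
univariate association with the outcome first and only then extracts a
principal component, so the resulting one-number summary per patient is both
low-dimensional and outcome-directed. This package implements that workflow
for all three outcome types with a common interface, cross-validated
threshold selection, and held-out evaluation.

## Screening statistics

The screening score $s_j$ is a null-evaluated test statistic, chosen so that
screening is closed-form, deterministic and comparable across features:

* **Survival.** The Cox partial-likelihood score test at $\beta = 0$:
  $$U_j = \sum_{i : \delta_i = 1} \left( x_{ji} - \bar x_{j, R(t_i)} \right),
  \qquad
  I_j = \sum_{i : \delta_i = 1} \operatorname{Var}_{R(t_i)}(x_j),
  \qquad z_j = U_j / \sqrt{I_j},$$
  where $R(t)$ is the risk set at event time $t$ and the risk-set variance is
  the population form. Tied event times are handled with the Breslow
  convention (every tied event sees the full tied risk set) — the simplest
  deterministic tie rule; users with heavily tied data should be aware the
  Efron variant would differ slightly. Censored samples contribute through
  risk sets only. The sign is positive when higher expression goes with
  higher hazard.
* **Continuous.** The t-statistic of the univariate least-squares slope,
  $t_j = r_j\sqrt{n-2}/\sqrt{1-r_j^2}$. A feature exactly collinear with the
  outcome has an infinite t; it is mapped to the largest representable
  double (with a warning) so that ranking and thresholding remain total.
* **Binary.** The logistic score test at slope $0$ with the intercept fixed
  at $\operatorname{logit}(\bar y)$:
  $U_j = \sum_i x_{ij}(y_i - \bar y)$,
  $I_j = \bar y (1-\bar y) \sum_i (x_{ij} - \bar x_j)^2$,
  $z_j = U_j/\sqrt{I_j}$. The centering in $I_j$ is the profile information
  that accounts for the intercept being a nuisance parameter. A score test
  was preferred over a Wald statistic from an iteratively fitted logistic
  model because it is closed-form, cannot fail to converge, and is immune to
  separation; the Wald flavour is available via `binary_stat = "wald"` for
  users who want to match fitted-model output.

All three statistics are invariant to per-feature location shifts and to
positive rescaling, so screening does not depend on the (monotone) expression
scale. Constant features score 0 with a warning rather than erroring:
real matrices contain flat rows and screening should simply drop them.

## Threshold grid and cross-validation

Candidate thresholds are `n_thresholds` points equally spaced on the quantile
scale of the training $|s_j|$, between the 0 and 0.95 quantiles (R's type-7,
linear-interpolation quantiles; duplicates collapsed). Equal spacing on the
quantile scale puts grid resolution where the scores actually are, and the
0.95 cap keeps the top of the grid from selecting an empty or near-empty
gene set. Screening is strict ($|s_j| > \theta$), so the monotonicity
property $\theta_1 < \theta_2 \Rightarrow S(\theta_2) \subseteq S(\theta_1)$
holds exactly.

For each fold $f$ of a $K$-fold partition, scores are recomputed on the
out-of-fold samples, features screened at each $\theta$, the leading PC
fitted on the out-of-fold block, and the held-in fold projected. The
objective is the held-out likelihood-ratio statistic of the outcome on the
projected PC — Cox LR for survival, Gaussian LR $n\log(\mathrm{TSS}/\mathrm{RSS})$
for continuous, binomial deviance difference for binary. The LR statistic
was chosen as the CV objective because it is defined identically across all
three outcome types and grows with association strength on the held-out
fold; the choice is recorded in the result object rather than asserted to
match any other implementation. The optimal $\theta$ maximizes the fold mean;
ties break toward the larger threshold (fewer genes — parsimony). A
threshold that empties a fold's screened set contributes statistic 0 (with a
message) instead of aborting, keeping the CV curve total across the grid.
Folds are seeded and stratified by event indicator or class label by
default, and the realized assignment is always part of the output so a rerun
from the emitted fold file is bit-identical; when a fold file is supplied it
*defines* the training set, which is what makes replay exact without a seed.

## PC fit, projection and prediction

The selected training block is centered per feature by its training mean —
no variance scaling. Scaling would overweight low-variance features and undo
the implicit weighting the screening statistic established; users who want
correlation-PCA can standardize beforehand. The loading vector $w$ is the
leading principal direction over features (unit Euclidean norm), with the
sign fixed so the largest-magnitude loading is positive — an arbitrary but
deterministic convention that makes results reproducible across linear
algebra backends. Held-out samples are projected as
$\mathrm{score}_i = \sum_j w_j (x_{ji} - c_j)$ with the *training* centers
$c_j$; the test set is never touched during scoring, screening, centering or
loading estimation.

Test-set association uses the classical pairings: the PC is split at its
median (`<=` goes to "low" — a fixed, documented side for ties) and compared
by log-rank/KM for survival or chi-square for binary; or kept continuous
for Pearson correlation (continuous outcome) or a two-sample t-test of PC by
class (binary). The t-test defaults to Welch's unequal-variance form (safer
when group spreads differ; `var_equal = TRUE` restores the pooled test). The
chi-square has no continuity correction by default — the correction
materially changes small-sample p-values and is switchable — and the odds
ratio $ad/bc$ gets the Haldane 0.5 adjustment only when a zero cell exists,
which is reported when it happens.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws a standard-normal latent factor $u$ per sample;
signal genes are $x_j = b_j u + \varepsilon$ with $b_j \sim U(0.5, 1.5)$ and
unit-normal noise; noise genes are independent unit normals. Outcomes follow
the simplest member of each family: exponential event times with hazard
$e^{\gamma u}$ under independent uniform censoring whose upper bound is
calibrated by root-finding so the *expected* censoring fraction equals the
requested rate; $y = \gamma u + N(0,1)$; or
$y \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\gamma u))$. With
$\gamma = 0$ the outcome is exactly independent of the matrix, giving a
clean null.

This is deliberately a fixture, not a model of tumor profiles: there are no
count distributions, library-size or batch effects, no gene–gene correlation
beyond the single factor, and censoring is independent of the linear
predictor only conditionally on $u$. Tests passing on these data demonstrate
the *algorithm* (honest cross-validation, signal recovery, calibration of
the held-out tests under the null), not performance on any particular real
cohort.

## Parameters and defaults

| Parameter | Default | Notes |
|---|---|---|
| `train_prop` | 0.67 | two-thirds training split, stratified by event/class |
| `n_thresholds` | 20 | grid points on the quantile scale of $|s|$ |
| `n_folds` | 10 | CV folds, stratified, seeded, always emitted |
| `binary_stat` | `"score"` | `"wald"` for fitted-model z |
| `summary_style` | per outcome | KM (survival), scatter (continuous), bar (binary); `"dichotomized"`/`"continuous"` override |
| `censor_rate` | 0.3 | simulator target censoring fraction |

The test suite and the acceptance script run the pipelines at 45–150 samples
and 30–500 genes with 3–10 folds — the scale of the cohort studies this
method is used on, and small enough that the full suite executes in a couple
of minutes. The null-calibration study uses 60-sample replicates at
`effect = 0` and checks that the held-out test rejects at close to the
nominal 5% level for every outcome type.

## Numerical and degenerate-input choices

* Strict screening means $\theta = \max|s|$ empties the set; that is an
  error outside CV and a logged statistic-0 inside it.
* `fit_pc()` requires at least two training samples; a single selected
  feature degenerates to the centered feature itself ($w = 1$).
* Validation errors always name the offending feature, sample or coordinate;
  missing values are rejected at load (pre-impute if needed) because silent
  imputation would change the statistics.
* Expression/clinical sample mismatches fail by default;
  `allow_intersection = TRUE` keeps the intersection and reports the dropped
  IDs.
* All seeded operations use isolated RNG state (`withr::with_seed`), so
  library calls never perturb a caller's random stream; derived seeds stay
  below $2^{31}$.

## Limitations

Only the first principal component is used (the held-out predictor is "the"
predicted PC); no shrinkage or soft-thresholding variants; no multivariable
adjustment of the test-set association; no multiple-testing correction of
the screening scores (selection is by threshold, not by p-value); forest
plots display user-supplied intervals verbatim with no meta-analytic
pooling. Proportional hazards and linearity of the PC effect are assumed,
not checked.
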