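---
title: "Models and methods behind glipnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glipnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`glipnet` links a longitudinal plasma lipidome to infant growth faltering
through five statistical stages. This vignette is the package's own account
of the models, the tunable parameters that matter, the numerical choices,
and what the synthetic-data tests do and do not establish.

## 1. Feature quality control

A raw feature table holds nonnegative intensities for study, blank, and
QC-dilution samples, plus expected and mean observed masses per feature.
Four metrics are computed per feature:

* **ppm deviation** = |mean observed − expected| / expected × 10⁶;
* **blank ratio** = mean study intensity / mean blank intensity;
* **zero fraction** over *study* samples only (the blank and dilution
  samples say nothing about biological missingness);
* **dilution r** = Pearson correlation of intensity with the dilution
  factor across the QC series, on the raw intensity scale (a
  `log_dilution` flag switches to log1p; which scale the convention
  intends is genuinely ambiguous).

Removal rules are strict inequalities at the printed thresholds
(ppm > 5, ratio < 5, zero fraction > 0.10, r < 0.9): a feature sitting
exactly on a threshold is retained. The rules are conjunctive, so the
survivor set is order-invariant; attribution of each removal to a step
follows the fixed order ppm → blank → zeros → dilution so an attrition
table can be reported. Metrics that cannot be evaluated (no blanks, fewer
than three dilution points, constant QC intensities) pass by default and
are logged — silence would hide a design problem, failure would punish a
feature for missing controls.

## 2. Signed weighted correlation network and eigenlipids

Pairwise Pearson correlations s_ij (pairwise-complete) are mapped through
a_ij = ((1 + s_ij)/2)^β. The *signed* transform keeps anticorrelated
lipids apart — the analysis asks which lipids move *together* over time.
β defaults to 18, a value at which lipid networks of this kind reach
approximate scale-free topology; `scale_free_fit` reports the r² of the
log-log connectivity fit (≈ 0.8 or better is considered adequate) so the
choice can be checked per dataset rather than trusted.

Clustering uses the topological-overlap dissimilarity
1 − (Σ_u a_iu a_uj + a_ij)/(min(k_i, k_j) + 1 − a_ij), average-linkage
hierarchical clustering, a fixed cut at 99 % of the maximum merge height,
and dissolution of clusters smaller than `min_size = 10` into the
unassigned pool (module 0). This replaces the dynamic hybrid tree cut of
the reference implementation: the full algorithm is considerably more
machinery, and on clearly separated structure the fixed cut recovers
planted partitions exactly (tested at ARI = 1 across 20 seeds); on weak
structure the two can legitimately differ, which is a known limitation.

Each module's **eigenlipid** is the leading left singular vector of the
standardized samples × lipids submatrix, scaled to unit variance, signed so
it correlates nonnegatively with the module mean profile, with variance
explained σ₁²/Σσ². Samples are child × visit observations pooled across
time; missing values are mean-imputed per lipid before the SVD (and
logged). The unassigned pool is summarized too (`ME0`), mirroring analyses
that carry the grey module as one more node.

## 3. Fixed-effects panel models

Growth and lipid trends use the within estimator: demean response and
covariates within child, then OLS — numerically identical to least squares
with child dummies (tested to 1e-10 against that oracle). The time
covariate is the visit index 1..5, not calendar weeks, matching the
convention that the trend coefficient is per *visit*; a different time
column can be passed. Standard errors are clustered by child with the
small-sample factor G/(G−1)·(N−1)/(N−K), K counting slopes plus absorbed
child intercepts; p-values use the normal approximation by default (t with
G−1 df behind a flag). Time-invariant covariates such as sex are rejected
with an explicit error — they are absorbed by the fixed effect, and a
silent NA would be worse. The sex×age interaction reported in some
analyses of such cohorts is not implemented: with child fixed effects the
main sex effect is not estimable and the interaction model is not
identified from the stated information.

`trend_screen` classifies features as up/down/flat at FDR < α using an
in-package Benjamini–Hochberg step-up (tested against `p.adjust`), and
`consecutive_paired_ttests` compares consecutive visits among children
observed at both, with star tiers at p < 0.01 / 0.001 / 0.0001.

## 4. Latent-class growth trajectories

The trajectory model is a K-class mixture of linear mixed models: class k
has mean B(age) β_k (natural cubic spline basis with knots at five age
quantiles plus intercept — with the five scheduled visit ages the basis is
saturated and interpolates any per-visit mean pattern), all classes share a
random intercept + slope covariance G and residual σ² (parsimony; the
reference behaviour of such fits), and sex enters the mean additively with
a common coefficient rather than the membership model. Children with
incomplete schedules contribute the Gaussian likelihood of their observed
visits only (missing at random).

Fitting is EM with exact conditional maximizations, so the observed-data
log-likelihood is non-decreasing at every iteration — this is asserted at
run time, not assumed. Computation is grouped by missingness pattern, so
each iteration costs a handful of small matrix factorizations. Because the
residual-based M-step approaches the GLS fixed point only linearly, a
final "mean polish" applies a few GLS steps for the trajectories (valid EM
steps with class labels as the only missing data, hence still monotone);
this makes the K = 1 fit agree with a generalized-least-squares oracle to
1e-6 and better. Initialization is k-means on child-level (mean, slope)
summaries; pure random assignment collapses all classes onto the grand
mean and was abandoned. Later restarts perturb the k-means labels. An
empty class (π_k < 1/(10n)) aborts the restart. Classes are relabelled by
ascending fitted trajectory at the first visit, making labels
deterministic. K is selected by AIC over 2–4.

**What the recovery tests establish.** The selection and recovery tests
simulate with no cross-lagged dynamics (`var_matrix = 0`), i.e. from the
latent-class model's own data-generating process, with class separation at
the stated "gap ≥ 3 standard deviations". Under the default generator the
within-child errors are AR-correlated; the mixed-model covariance is then
mis-specified and AIC systematically overselects K — a real phenomenon,
not a bug, and the reason the selection-consistency claim is scoped to the
well-specified world.

## 5. Panel VAR by system GMM

The dynamic model is Y_it = Σ_l A_l y_i,t−l + v_i + e_it. Least squares
with fixed effects is biased for lagged responses in short panels
(Nickell bias ≈ −(1+ρ)/(T−1), demonstrated in the acceptance tests), so
estimation is GMM:

* **Transform**: first differences (fd) or forward orthogonal deviations
  (fod, the default — it preserves orthogonality of the transformed errors
  on unbalanced panels). fod subtracts the mean of the *available* future
  observations with factor √(m/(m+1)).
* **Instruments**: period-specific blocks of lagged levels of all
  endogenous variables; dated t−2 and earlier under fd (Δe_t involves
  e_{t−1}) but t−1 and earlier under fod (the transformed error at t
  involves only e_t..e_T). Depth is configurable (default: full history);
  `collapse` sums blocks into one column per lag distance. Missing entries
  are zero-filled and all-zero columns dropped. With system GMM a levels
  equation is added, instrumented by lagged first differences, with
  exogenous variables instrumenting themselves; time-invariant exogenous
  variables (sex) enter *only* the levels equation, since the transform
  annihilates them — an algebraic necessity worth stating against the
  habit of "adjusting for sex" everywhere.
* **Weighting**: one-step uses the fd H-matrix on differenced rows and
  identity blocks elsewhere; two-step re-weights per equation with the
  clustered moment covariance of one-step residuals. Equations share X and
  Z and are estimated one at a time, which under this block-diagonal
  weighting is identical to joint estimation. Singular weighting matrices
  are ridge-regularized with a loud warning.
* **Inference**: two-step standard errors carry the Windmeijer
  finite-sample correction *by default*. Without it the SEs are downward
  biased: in a null simulation (diagonal A, N = 400, T = 5) the cross-edge
  false-positive rate at α = 0.05 was 0.125; with the correction ≈ 0.057.
  A `windmeijer = FALSE` flag restores the uncorrected estimator.
* **Diagnostics**: Hansen J summed over equations with
  df = k·(instruments − parameters) (χ² size verified by Monte Carlo in
  the exactly-χ² single-equation case); Andrews–Lu MMSC
  (J − penalty·(c − b)) for lag selection over {1, 2}, ties toward the
  smaller order; companion-matrix eigenvalues for stability (strictly
  inside the unit circle).

The temporal ("G-association") network takes every lag-1 coefficient with
p < α as a directed edge source → target, including self-loops; the
pipeline standardizes endogenous variables first so edge weights are
comparable across variables.

Known limitations: the Hansen-J invariance to nonsingular instrument
recombination is a mathematical property of the estimator but has no
dedicated test, because the instrument matrix is internal to `fit_pvar`;
and no impulse-response or variance-decomposition machinery is provided.

## 6. The synthetic cohort

`simulate_study` states one concrete world: children at visit weeks
12/24/52/78/104; latent growth classes with linear-in-visit trajectories
(defaults: a persistently low class at proportion 0.25, a high declining
class at 0.32, a steeply declining class at 0.43 — proportions follow the
variant of the published shares that sums to one); sex Bernoulli(0.5)
entering the growth mean additively; a stacked state
(WAZ, LAZ, WLZ, module signals) following a stationary VAR(1) with child
fixed effects (burn-in 50 periods); lipids equal to their module's
standardized latent signal attenuated by √r plus independent √(1−r) noise,
so any two same-module lipids correlate at exactly r (default 0.8);
missing-at-random Bernoulli dropout after the first visit (default 0.10).
VAR steps are per visit index, not calendar week — the dynamic model
treats visits as the clock, matching the time-trend convention above.
Lipids are generated on a standardized log-like scale because the network
and panel stages operate on z-scores anyway.

What it does **not** emulate: real mass-spectral artifacts (the raw-feature
generator plants idealized violations), calendar-time dynamics between
unevenly spaced visits, informative dropout, non-Gaussian tails, and
lipid–growth effect sizes calibrated to any particular cohort (the true
cross-lagged matrices are user-chosen). A green recovery test therefore
establishes correctness of the estimators on their own model class, not
field validity of any biological conclusion.
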