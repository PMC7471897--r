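---
title: "Ordinal invasiveness modelling for subsolid lung nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal invasiveness modelling for subsolid lung nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulord)
```

## The problem and the model

Persistent subsolid nodules on chest CT frequently represent lung
adenocarcinomas whose degree of histological invasiveness spans an ordered
spectrum: pre-invasive lesions (H1), minimally invasive adenocarcinoma
(H2), and invasive adenocarcinoma (H3). Because management decisions
(follow-up interval, extent of resection) track that ordering, the package
models the three classes jointly with a cumulative-logit proportional-odds
regression rather than collapsing them into a binary outcome:

$$P(Y \le j \mid x) = \mathrm{logit}^{-1}(\alpha_j - x^\top\beta), \qquad
j \in \{1, 2\},$$

with one slope vector $\beta$ shared across both cutoffs and one intercept
per cutoff. The orientation is chosen so that a positive slope shifts
probability mass toward more invasive classes; exponentiated slopes are
then odds ratios greater than 1 for risk-increasing features, and a single
coefficient per predictor answers both clinical questions (H1 vs H2/H3 and
H1/H2 vs H3) at once. Predictors are centered by their training means
before fitting; the centers are stored in the fit, so predictions for raw
feature values are identical whether or not the caller pre-centers
(`fit_proportional_odds()`, `predict_class_probs()`).

Two two-predictor models are the analysis mainline: nodule `volume_log`
(base-10 log of the segmented volume in mm^3) combined with one
attenuation feature, either the functional principal component score
`FPC1` (Model 1) or the 87.5th-percentile attenuation `q875_hu`
(Model 2).

## Features

`compute_geometric_features()` works on the segmented binary mask: volume
is the voxel count times the voxel volume; the maximum diameter is the
largest pairwise 3-D distance between in-mask voxel centers (computed
exactly on the mask surface voxels); the minimum diameter is the smallest
extent of the PCA-aligned bounding box of the voxel centers. Workstation
vendors do not publish their diameter rules, so these two conventions are
documented choices, validated against analytic digital ellipsoids in the
test suite (agreement within one voxel diagonal). The consolidation ratio
divides the externally measured solid-component maximum diameter by the
nodule maximum diameter and is zero exactly for non-solid nodules.

`compute_attenuation_features()` works on the in-mask HU values or on a
`(hu_bin_left, count)` histogram (bin midpoints weighted by counts):
sample mean and SD, moment skewness $m_3/m_2^{3/2}$, *non-excess*
kurtosis $m_4/m_2^2$ (a normal sample sits near 3 — the convention that
makes kurtosis values around 2–4 for these nodules), and
linear-interpolation quantiles at probabilities $(k-1)/(n-1)$ (R type 7)
for Q.50, Q.75, Q.875 and the IQR.

## Attenuation curves, the LQD transform and FPCA

Each nodule's HU histogram is smoothed with a Gaussian kernel
(`stats::density`) on a 1-HU grid spanning $[-1024, 400]$; the default
bandwidth is Silverman's rule on the voxel sample. The density is floored
at $\delta = 10^{-6}$ per HU and renormalized: the floor keeps the
log-quantile-density transform finite at the support edges and perturbs
downstream scores by less than $10^{-3}$. A side effect is that the two
extreme grid points of the transform ($t = 0, 1$) reflect the floor level
rather than the nodule; this near-constant offset is common to all curves
and is absorbed by the FPCA mean.

Densities are compared in log-quantile-density space,
$\psi(t) = -\log f(Q(t))$ on $t \in [0, 1]$, which removes the
positivity and unit-integral constraints so that linear (functional PCA)
methods apply. The quantile function is obtained by inverting the
trapezoid CDF on a 101-point $t$ grid. The inverse map
(`lqd_inverse()`) integrates $\exp\psi$ on a spline-refined grid; the
round-trip is accurate to about $10^{-5}$ for densities whose quantile
density is resolved at the grid — a density with a *deep* valley between
modes (quantile density spiking by four orders of magnitude inside one
grid step) is not representable at this resolution, which is the relevant
resolution limit to keep in mind for strongly bimodal nodules.

`fit_fpca()` eigendecomposes the sample covariance operator of the
centered LQD curves under trapezoid quadrature weights. Eigenfunctions
are orthonormal in the weighted inner product, eigenvalues are
non-increasing, and variance fractions are eigenvalues over the total
trace. Because eigenvector signs are arbitrary, each component is flipped
so that its score correlates positively with Q.875 when that feature is
available (high FPC1 = heterogeneous, high-attenuation curve), with a
fallback sign rule (positive integral of the eigenfunction on
$t \in [0.75, 1]$). Two components are retained by default; the second is
kept for reporting but plays no role in the final models.

## Feature screening

`screen_features()` ranks candidates by binary ROC-AUC at each ordinal
cutoff. AUC is the tie-corrected Mann–Whitney statistic; its confidence
interval and the test against 0.5 use the DeLong variance (the exclusion
rule "AUC significantly above 0.5 at P < 0.001" is implemented as a
DeLong z-test). Operating points maximize Youden's J over midpoints between
consecutive distinct scores, reporting the more sensitive threshold on
ties, with the direction ("> t" vs "<= t") chosen automatically.

`confounder_plot_data()` gives each feature two coordinates: absolute
Spearman correlation with the ordinal class rank (similarity to the
response) and with a reference predictor (similarity to `volume_log`).
Rank correlation was chosen because it is invariant under monotone
transforms and handles the mixed scales of geometric and attenuation
features; the "recommended" rule (above the response-similarity median,
below the reference-similarity median) is a documented heuristic for the
top-left corner of the plot, not a published cutoff.

## Interpretation and diagnostics

`odds_ratios()` exponentiates coefficients and their Wald limits
(z = 1.96). `quartile_probability_change()` propagates estimation
uncertainty by simulation: parameter vectors are drawn from the
multivariate normal with the fit's mean and covariance (1000 draws by
default; the draw count is a precision choice, with Monte-Carlo error
scaling as $n^{-1/2}$), and class probabilities are contrasted between
the predictor's cohort quartiles with the other predictor held at its
cohort mean — holding companions at the mean is this package's
conditioning convention. Draws are taken as-is; in rare draws the two
intercepts can cross for very uncertain fits, which shows up as a
negative middle-class "probability" in that draw and averages out.

`po_diagnostics()` checks proportionality numerically: per-cutoff binary
logistic slopes (flagged when they differ by more than twice the pooled
SE) and an ordinality table of observed vs model-implied class-conditional
feature means. `deviance_test()` is a likelihood-ratio test of the
proportional-odds fit against the non-proportional cumulative-logit model
(separate slopes per cutoff, fitted by the same Newton engine under the
constraint that category probabilities stay positive), on
$(J-2)\,p$ degrees of freedom. The summed-binary-logit surrogate
sometimes used for this comparison was considered and rejected: its two
likelihood scales differ systematically (the statistic is negative in
expectation for identical fits) and, as a composite-likelihood ratio, it
has no chi-square calibration; the test suite verifies the implemented
test's null rejection rate empirically (200 simulated cohorts of
n = 500).

Numerics: the MLE is computed by Newton–Raphson with analytic gradient
and Hessian and step-halving, to a score tolerance of $10^{-8}$
(with a numerical floor at $10^{-5}$ for raw-scale features whose
likelihood reaches machine precision first); the covariance is the
inverse observed information. Complete separation is reported as an
explicit error when a standardized slope exceeds 30 (i.e.
$|\beta_j|\,\mathrm{sd}(x_j) > 30$, essentially deterministic class
assignment), rather than returning divergent estimates.

## Validation

`monte_carlo_cv()` repeats a stratified 80/20 split (per-class test size
rounded half-up, minimum one), refits on the training rows — feature
centering is recomputed per fold, while the FPCA basis is fitted once on
the whole cohort, matching an analysis in which the curve basis is a
cohort-level construction — and evaluates on the held-out rows at both
cutoffs: AUC, the scaled Brier score
$100\,(1 - \mathrm{Brier}/\bar p(1-\bar p))$ (0% = prevalence-only
predictor, 100% = perfect), and the average calibration error EAVG, the
mean absolute gap between predictions and a lowess
(span 2/3, *no* robustness iterations — robust reweighting would treat
0/1 outcomes as outliers) observed-frequency curve. Degenerate repeats
(a single-class test side, or a separated training fold) are recorded
missing, excluded from summaries and counted, never imputed. Summaries
are the mean and 2.5/97.5 linear-interpolation percentiles over repeats;
200 repeats is the default. `multiclass_report()` adds per-class
one-vs-rest AUCs for the ordinal and LDA classifiers; LDA uses class
means, a pooled within-class covariance and empirical priors.

## The synthetic cohort

The study's image data are not public, so `generate_mechanistic_cohort()`
produces cohorts with the statistical structure the analysis assumes,
and every claim the test suite makes about the pipeline is a claim about
this generator. Defaults encode the study conditions: 31/64/132 nodules
per class; class-median volumes 1362/1297/3436 mm^3 with lognormal
(log10) SD 0.46; a two-component HU mixture — ground-glass
$N(-700, 60^2)$, solid $N(-100, 80^2)$, truncated to $[-1024, 400]$ —
whose solid fraction is drawn per class from intervals
H1 $[0, 0.17]$, H2 $[0.10, 0.34]$, H3 $[0.25, 0.65]$, chosen once so the
implied class mean attenuations ($-700 + 600\,\bar s$) match the reported
class means near $-649/-569/-432$ HU; ellipsoidal masks with max/min
axis ratio in $[1.2, 1.9]$ at $0.7 \times 0.7 \times 1.0$ mm voxels; a
latent-Gaussian correlation of 0.3 between volume and solid fraction
(the reported volume–attenuation association is "modest", around 0.3,
and the knob's default is a choice, not a measured value). The solid
component occupies the nodule core and its equivalent-sphere diameter is
the solid diameter. One RNG stream per cohort makes generation
bit-reproducible.

What the generator does **not** emulate: CT texture and scanner noise,
reconstruction-kernel effects, irregular or lobulated shapes, vessels or
partial-volume voxels, multi-focal solid components, or growth over
time. Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative assumptions — not clinical
performance on real nodules; the synthetic attenuation signal is in fact
cleaner than the published cohort's (cross-validated AUCs on the default
synthetic cohort come out higher than the 0.83–0.87 reported for real
data).

`generate_po_cohort()` is the second, direct generator: features in,
classes drawn exactly from the cumulative-logit model with known
coefficients. It is the ground truth for parameter-recovery coverage,
the deviance-test null calibration, and the cross-validated-AUC oracle
(compared against brute-force AUC at $n = 10^6$).

## Problem sizes used by the checks

The shipped checks run at deliberately modest sizes: parameter recovery
at n = 5000 over 50 seeds; deviance-test calibration on 200 cohorts of
n = 500; FPCA mode recovery at n = 500 curves; CV oracle at n = 1000
with 200 repeats; the end-to-end pipeline example at 12/24/48 nodules
per class; and the full reproduction script at the study's 31/64/132.

## Known limitations

- Diameter conventions (3-D pairwise maximum, PCA-box minimum) are
  assumptions; workstation values may differ systematically.
- The LQD grid (101 points) cannot represent densities with deep
  inter-mode valleys; such nodules would alias in FPC space.
- Partial proportional-odds models are out of scope; the deviance test
  only contrasts full proportionality with fully cutoff-specific slopes.
- The quartile-change conditioning (companion predictors at their means)
  is one of several defensible conventions.
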