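---
title: "Attenuation-histogram analysis of paired inspiration/expiration CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attenuation-histogram analysis of paired inspiration/expiration CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hushift)
library(dplyr)
```

## The measurement problem

In idiopathic pulmonary fibrosis (IPF), surfactant dysfunction raises alveolar
surface tension and parts of the parenchyma collapse on expiration. Collapsed
tissue is denser, so on CT it shows an abnormally large attenuation increase
between full inspiration and maximal expiration. `hushift` quantifies that
shift from a *paired* inspiration/expiration scan and a lobe-label mask,
treating each lobe's voxels as an unordered set of Hounsfield-unit (HU)
values. Because only value distributions are compared, no voxel-wise
registration between the breathing states is needed — deformable registration
between inspiration and expiration is exactly the step this design avoids.

Five measures are computed per region (five lobes and the total lung):

* **mean HU (expiration)** — overall expiratory density;
* **skewness (expiration)** — `m3 / m2^1.5`; healthy aerated lung is strongly
  right-skewed, collapse shifts mass rightward and lowers skewness;
* **kurtosis (expiration)** — the *non-excess* `m4 / m2^2`, Gaussian
  reference 3; a value below 3 means a broader (platykurtic) histogram;
* **mean-HU ratio (exp/insp)** — 1 when nothing changes, falling toward 0 as
  expiratory density rises (both means are negative in aerated lung);
* **ΔP₍₋₂₅₀ HU₎** — the percentile at which −250 HU sits in the inspiratory
  distribution minus the same percentile in expiration. −250 HU is taken as
  the attenuation of alveolar collapse; a patient at the 93rd percentile in
  inspiration and 73rd in expiration scores ΔP = 20. Expiration is denser,
  so the statistic is positive, and larger values mean more tissue crossed
  the collapse threshold.

All moments are population (biased) central moments of the **raw voxel
values**, not of binned counts: the 1-HU-bin histograms that
`histogram_export()` writes are a display format, and at lobar sample sizes
(10⁴–10⁷ voxels) the small-sample moment correction is far below measurement
noise. The percentile is the left-continuous empirical CDF times 100
(`100 · mean(values ≤ threshold)`). Voxels are clamped to [−1024, 200] HU
before any computation — the range keeps soft-tissue-attenuation collapsed
parenchyma while discarding reconstruction outliers; both the clamp and the
−250 HU threshold are configurable through `analysis_config()`.

```{r worked-example}
insp <- c(rep(-800, 93), rep(-100, 7))   # 93% of voxels at or below -250 HU
exp_ <- c(rep(-800, 73), rep(-100, 27))  # 73% in expiration
delta_p(insp, exp_, threshold = -250)
```

## Clinical pipeline

`build_cohort()` turns raw PFT and event tables into one analysis row per
patient, with an exclusion ledger so every input patient is accounted for
exactly once (`excluded_patients()`).

* **Baseline pairing.** The PFT closest to the CT date is the baseline; the
  pairing is rejected beyond ±50 days (ties resolve to the earlier visit).
* **One-year interpolation.** Follow-up FVC% values arrive on irregular
  schedules, so the value at exactly one year is read off a least-squares
  polynomial in time. Ordinary polynomial bases of degree 1–4 are fitted
  and the Gaussian AIC selects among them; ordinary polynomials were chosen
  over fractional-polynomial bases because only they make a fourth-degree
  cap unambiguous. The degree is additionally capped at `n_visits − 2`, keeping
  one residual degree of freedom so noise is never interpolated exactly; two
  visits force a straight line. On noiseless polynomial data every
  admissible fit is exact, the AIC tie resolves to the lowest degree, and
  the day-365 value is recovered to numerical precision (this is tested).
  All of a patient's visits enter the fit, including pre-CT ones.
* **Outcome assignment.** Death or transplantation within 1095 days is an
  event ("3 years" is not defined to the day anywhere authoritative; 3 × 365
  is the documented choice). Surveillance status requires demonstrated
  follow-up across the whole window; anything else is lost to follow-up and
  excluded. `event_type` is carried on every record so the
  transplant-excluded sensitivity analysis is a row filter, not a second
  pipeline.

## Statistics

Two-sided tests throughout. Pearson correlations use the exact t transform
on n − 2 degrees of freedom. The Mann–Whitney U test uses midranks; with
both groups at 8 or fewer observations and no ties the p-value is exact
(doubled smaller tail of the exact U distribution), otherwise a normal
approximation with tie-corrected variance and continuity correction is used.
The approximation is within 0.02 of the exact tail by the time the exact
branch hands over (about 8 per group); at very small sizes it is materially
worse, which is precisely why those sizes always take the exact branch.
Upper-versus-lower-lobe comparisons (RUL–RLL, LUL–LLL) are paired t tests on
within-patient differences, with degenerate zero-variance differences
reported explicitly rather than erroring. No multiple-testing correction is
applied across the handful of measures; tables report means ± SD next to
the rank test because that is the conventional presentation, mismatched as
it is.

Prognostic models are maximum-likelihood logistic regressions
(`stats::glm`, IRLS, ≤100 iterations, tolerance 1e−8) with predictors
entered untransformed and unstandardized. Separation is detected from
diverging linear predictors and flagged on the result. The parsimonious
model comes from greedy backward elimination: at each step the deletion
with the lowest AIC is applied if it strictly lowers the current AIC; AIC
ties break toward the predictor with the largest Wald p (the step criterion
is not uniquely determined by "contributed the least"; AIC-guided deletion
is the documented operationalization). The AUC of the fitted probabilities
is the midrank Mann–Whitney estimator with a DeLong structural-components
variance and a Wald 95% CI truncated to [0, 1]; reported AUCs are apparent
(in-sample) — no cross-validation is attempted, matching the design being
emulated.

One selection property deserves emphasis: a pure-noise predictor survives
AIC-guided deletion whenever its likelihood-ratio χ²₁ exceeds 2, which
happens with probability ≈ 0.157 under the null. With several noise
predictors the probability that backward elimination returns *exactly* the
generating support therefore plateaus near 0.84^k (≈ 0.5 for k = 4), no
matter how strong the true signals are. This is a property of AIC itself,
not of the implementation; the test suite measures it and the greedy path
is instead validated against the exhaustive all-subsets AIC minimum, which
it attains in ≥ 95% of simulated cohorts.

## What the synthetic generators emulate

**Phantoms.** `generate_phantom_pair()` builds an abstract partitioned box —
right lung split apex-to-base into RUL/ML/RLL, left into LUL/LLL, with a
background shell — because the histogram measures are geometry-free. Each
lobe is a two-compartment Gaussian mixture: aerated tissue (−850 ± 50 HU,
expiratory shift +50 HU) and collapsing tissue (−450 ± 80 HU, shift
+400 HU), with independent voxel noise (SD 20 HU) added in expiration and
everything clamped to [−1024, 200]. Default collapse fractions encode the
basal-predominant gradient (RUL/LUL 0.10, ML 0.07, RLL/LLL 0.30 — lower
lobes three times the upper, middle lobe lowest). These values were chosen
once to land the lobe-wise measures in the clinically reported ranges
(e.g. analytic ΔP ≈ 10 in upper and ≈ 30 in lower lobes).

`phantom_truth()` returns the *exact* population values of all five
measures from closed forms: raw moments of each clamped normal via the
truncated-normal recursion plus boundary point masses, mixed over
compartments and (for the total lung) over lobes by voxel count. The clamp
is handled exactly rather than ignored; the percentile at −250 HU is
clamp-invariant because both clamp bounds stay on their own sides of the
threshold. Empirical metrics converge to these truths at the Monte-Carlo
1/√n rate, which is what makes the phantom an independent oracle for the
metric code. What phantoms do **not** emulate: anatomy, airways and
vessels, scanner noise texture, partial-volume and reconstruction-kernel
effects, or contrast agents — a pass on phantoms validates the estimators,
not the imaging physics.

**Cohorts.** `generate_cohort()` draws one record per patient in two
subgroups (surveillance n = 37, death/transplantation n = 29 by default)
whose measure distributions default to the published subgroup means and
SDs, total-lung and lobe-wise. Range-bounded measures are monotone
transforms of latent Gaussians — scaled logit for the mean-HU ratio on
(0, 1) and for ΔP on (−100, 100), `1 + lognormal` for kurtosis so the
kurtosis > 1 bound always holds — with latent parameters moment-matched
numerically so the natural-scale means/SDs hit the targets (a naive
parameter-level logit would bias the ΔP mean by about 2 points). The
published tables give only marginals; the joint structure is a modelling
choice, implemented as a single latent severity factor giving exchangeable
correlation ρ = 0.5 in magnitude with physiological signs (ΔP and mean HU
load positively on severity; ratio, skewness, kurtosis and FVC%
negatively). Within-patient skewness–kurtosis pairs are *not* constrained
to the sample-moment inequality `kurt ≥ skew² + 1` — the marginals are
emulated, not a common underlying histogram. FVC% series are a linear
per-year decline (subgroup delta FVC% defaults) plus visit noise (SD 3
percentage points) on ~120 ± 30-day schedules out to 750 days, with the
baseline visit at −4 ± 18 days (truncated to ±50) and a guaranteed
follow-up at ≥183 days; event times are 604 ± 294 days truncated to the
3-year window, and 6/29 of events are transplants. Every generated patient
satisfies the pipeline's inclusion criteria by construction, which the
suite verifies.

All generators are driven by a single integer seed and restore the caller's
RNG state; identical spec + seed is bit-identical output.

## Numerical choices and problem sizes

* Moments: single-pass centered sums in double precision; zero-variance,
  n < 4, empty-region and shape-mismatch inputs always error.
* Phantom oracle checks run at 10⁶ in-lung voxels across 20 seeds; each
  measure's across-seed mean must sit within 3 Monte-Carlo SEs of truth.
* Mann–Whitney calibration uses 5000 null replicates at the 37/29 subgroup
  sizes (type-I 0.05 ± 0.01); exactness is enumerated for all no-tie size
  pairs up to 6 + 6.
* DeLong SEs are checked against a 2000-resample stratified bootstrap at
  n = 66 (within 15% relative), and against an independent reference
  implementation to 1e−8.
* Variable selection is profiled on 200 cohorts of n = 500; the skewness-only
  model's AUC is checked against the binormal closed form
  Φ(|μ₁−μ₂|/√(σ₁²+σ₂²)) over 500 cohorts of n = 66.

These sizes were chosen as the smallest at which the Monte-Carlo tolerances
above are meaningful.

## Known limitations

* Defaults reproduce *distributional* structure of a single published
  cohort; nothing here validates transportability across scanners,
  reconstruction kernels or breathing-instruction protocols.
* Lobe masks are consumed, never computed; segmentation quality is upstream
  of everything.
* The exchangeable-severity correlation is a stand-in for an unreported
  joint distribution; statistics sensitive to the correlation structure
  (e.g. multivariable coefficients) should be read accordingly.
* Apparent AUCs are optimistic in small cohorts; the package reports them
  for fidelity, not as honest out-of-sample performance.
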