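# hushift

Quantitative analysis of paired inspiration/expiration thoracic CT for
idiopathic pulmonary fibrosis (IPF). In IPF, surfactant dysfunction makes
parts of the parenchyma collapse on expiration; collapsed tissue is denser,
so the expiratory attenuation histogram shifts right and broadens far more
than in healthy lung. `hushift` measures that shift per lobe and for the
total lung, links it to pulmonary-function trajectories and three-year
outcomes, and fits the prognostic models that ask whether the imaging signal
adds to spirometry. It is aimed at quantitative-imaging researchers working
with lobe-segmented inspiration/expiration CT and longitudinal FVC records.

## The measures

For a region's voxel values (HU, clamped to [−1024, 200]) in each breathing
state, the package computes, in expiration: the mean HU, the skewness
m₃/m₂^{3/2}, and the non-excess kurtosis m₄/m₂² (Gaussian = 3; below 3 is
platykurtic); across the two states: the mean-HU ratio exp/insp, and the
percentile-shift statistic

ΔP₍₋₂₅₀ HU₎ = P_insp(−250 HU) − P_exp(−250 HU),

where P(t) is the percentile at which threshold t sits in the empirical
attenuation distribution (100 · fraction of voxels ≤ t). A patient on the
93rd percentile in inspiration and the 73rd in expiration scores ΔP = 20.
Because only value distributions are compared, no registration between the
breathing states is required. −250 HU approximates the attenuation of
alveolar collapse and is configurable.

Downstream, the package pairs each CT with its closest PFT (±50 days),
interpolates FVC% to exactly one year via AIC-selected polynomial fits
(degrees 1–4, capped at n−2), assigns three-year outcomes
(death/transplantation vs clinical surveillance), and provides Pearson
correlation tables, Mann–Whitney subgroup comparisons (exact for small
groups), upper-vs-lower-lobe paired t tests, and logistic models — FVC%-only,
CT-measures, and an AIC-backward-eliminated parsimonious model — with DeLong
95% CIs on the AUC and a transplant-excluded sensitivity rerun. Seeded
generators supply two-compartment attenuation phantoms with analytic ground
truth and synthetic cohorts with the published subgroup distributions, so
the whole pipeline is testable without clinical data.

## Worked example

```r
library(hushift)
library(dplyr)

# A 64^3 phantom: basal-predominant collapse, paired phases, lobe mask
spec <- phantom_spec(grid_shape = c(64, 64, 64), seed = 7)
pair <- generate_phantom_pair(spec)
compute_metrics(pair$insp, pair$exp, pair$mask)
#>   region  n_exp mean_hu_exp skewness_exp kurtosis_exp mean_hu_ratio delta_p_250
#> 1 RUL     37800       -725.        2.49          7.83         0.895        9.87
#> 2 ML      21600       -749.        3.09         11.7          0.910        6.74
#> 3 RLL     48600       -575.        0.876         1.93         0.788       29.5
#> 4 LUL     48600       -725.        2.49          7.81         0.895        9.87
#> 5 LLL     59400       -574.        0.868         1.91         0.787       29.7
#> 6 TOTAL  216000       -652.        1.48          3.45         0.846       19.4
```

The lower lobes (RLL, LLL) carry three times the collapsing-tissue fraction
of the upper lobes, and every measure responds as it should: ΔP ≈ 30 vs ≈ 10
percentile points, mean-HU ratio 0.79 vs 0.90, and markedly lower skewness
and kurtosis (1.9 — platykurtic broadening) where collapse is strong.
`phantom_truth(spec)` returns the closed-form population values these
estimates converge to.

```r
# A synthetic 37 + 29 cohort at the published subgroup distributions
coh <- generate_cohort(cohort_spec(seed = 7))
compare_subgroups(coh) |> select(measure, mean_surveillance, mean_event, p)
#>   measure          mean_surveillance mean_event        p
#> 1 delta_p_250                  9.91       13.5    0.0131
#> 2 mean_hu_ratio                0.752       0.684  0.00272
#> 3 mean_hu_exp               -569.       -496.     0.00148
#> 4 skewness_exp                 0.937       0.530  0.000199
#> 5 kurtosis_exp                 3.56        2.70   0.00193
#> 6 baseline_fvc_pct            72.3        67.5    0.301
#> 7 delta_fvc_pct               -6.27       -2.26   0.0496

suite <- run_model_suite(coh)
glance(suite) |> filter(analysis == "primary") |> select(model, aic, auc, auc_ci_low, auc_ci_high)
#>   model          aic   auc auc_ci_low auc_ci_high
#> 1 fvc           92.4 0.575      0.435       0.715
#> 2 ct            78.3 0.821      0.722       0.920
#> 3 parsimonious  77.1 0.795      0.689       0.901
```

In this draw the CT-measure models clearly outperform the FVC%-only
reference (AUC 0.82/0.80 vs 0.58, DeLong CIs shown), echoing the pattern
the measures were designed to capture. `tidy(suite)` gives the coefficient
tables, including the sensitivity refits on the transplant-excluded subset;
`plot_lobe_profile()`, `plot_attenuation_histogram()` and
`autoplot(model)` draw the standard displays.

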