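# adaptbias

Do physicians who supervise AI-propagated target volumes inherit the
propagation algorithm's errors? In online adaptive radiotherapy of bladder
cancer, the clinical target volume (CTV) is carried from the reference
image to the anatomy of the day by a registration algorithm, and a
physician reviews and corrects it before re-planning. `adaptbias`
implements the complete cross-over analysis of that question for R:
volumetric test-segment geometry, consensus segmentation, dosimetric
summaries, the trial statistics, and a synthetic cohort that emulates the
study design end to end with exactly known ground truth.

For each localized *test segment* where two propagation algorithms
disagree by more than 5 mm, the remaining signed mean distance to the
local ground truth (dMDA_GT, mm) is measured before and after each
physician's adjustment. The primary endpoint is the proportion of pairwise
comparisons in which the algorithm that was worse before adjustment is
still worse afterwards; under unbiased correction that proportion is 0.5,
and it is tested with the exact one-sided binomial test
(H1: proportion ≥ 0.65, α = 0.025). The quantitative adjustment law is a
mixed linear model with no intercept,

    dMDA_adjusted = β · dMDA_unadjusted + b_segment + b_physician + ε,

with physician-specific slopes around the global β; β = 1 is pure
automation bias, β = 0 perfect correction.

The toolbox covers:

- **mm-aware mask geometry** — expansion/contraction via exact anisotropic
  Euclidean distance transforms, surface extraction, directed/symmetric
  mean distance to agreement, signed deviations, octant classification,
  iso-surface patch areas (`morph_offset()`, `extract_surface()`,
  `compute_mda()`, `sign_dmda()`, `patch_area()`).
- **Test-segment pipeline** — the rim-Boolean identification recipe,
  fraction screening, complementary segments, and the primary-endpoint
  pairwise bookkeeping (`identify_test_segments()`, `screen_fractions()`,
  `build_pairwise_comparisons()`, `study_report()`).
- **STAPLE consensus** — binary expectation-maximization over multiple
  readers with per-rater sensitivity/specificity (`staple()`).
- **Dosimetry** — inter-shell volumes by morphological closing, PTV margin
  expansion, power-mean gEUD (a = −20), margin-wise coverage summaries
  (`intershell_volume()`, `geud()`, `coverage_summary()`).
- **Trial statistics** — exact binomial test and power, Clopper-Pearson
  intervals, Fisher's exact test, a carryover-balanced cross-over schedule
  generator, the mixed adjustment model with `tidy()`/`glance()`/
  `autoplot()` methods, and a location-adjusted k-sample Ansari-Bradley
  scale test.
- **Synthetic cohort** — bladder-like CTVs, analytic (hence exactly
  invertible) deformations, per-algorithm error bumps, physician
  correction profiles, and the full seeded study generator
  (`generate_study()`, `simulate_records()`).

Masks are read and written as NIfTI-1 volumes, tables as CSV; a thin
command-line front end lives at `inst/cli/adaptbias.R`
(`power`, `schedule`, `simulate`, `report`).

## Worked example

Reproduce the trial's power calculation, then simulate a paper-scale study
(13 physicians, 10 cases, 13 segments, 3 algorithms) on a 64³ lattice at
2 mm and run the primary analysis:

```r
library(adaptbias)

exact_binomial_power(n = 130, p0 = 0.5, p1 = 0.65, alpha = 0.025)
#> # A tibble: 1 × 5
#>       n critical_k achieved_size power alpha_reachable
#>   <dbl>      <int>         <dbl> <dbl> <lgl>
#> 1   130         77        0.0216 0.928 TRUE

cfg   <- default_study_config(grid_dim = c(64, 64, 64), spacing = c(2, 2, 2))
study <- generate_study(cfg, seed = 11)
study_report(study$records)$table1
#> # A tibble: 3 × 7
#>   subgroup           positives     n proportion ci_lower ci_upper  p_exact
#>   <chr>                  <int> <int>      <dbl>    <dbl>    <dbl>    <dbl>
#> 1 all                      150   169      0.888    0.830    0.931 9.38e-27
#> 2 above_median              70    78      0.897    0.808    0.955 8.72e-14
#> 3 at_or_below_median       80    91       0.879    0.794    0.938 2.21e-14

fit_adjustment_model(study$records)
#> <adjustment_model_fit> ML fit, 507 obs (13 physicians x 13 segments)
#>   global slope 0.6925 +/- 0.0211; residual SD 1.97 mm
#>   physician slopes 0.3897 .. 0.9762 (heterogeneity p = 7.383e-13)
```

Read: with a test of design power 0.928, 150 of 169 pairwise comparisons
stay positive (88.8%, exact CI 0.830–0.931) — the worse algorithm almost
always stays worse after supervision — and the physicians carry about 69%
of each algorithm's error into their adjusted contour (global slope 0.69),
with slopes per physician from 0.39 to 0.98. `autoplot()` on the fit draws
the observed-vs-fitted adjustment lines per physician;
`plot_comparison_summary()` displays the proportion table.

## Package layout

- `R/` — geometry (`mask.R`, `geometry.R`), segment pipeline
  (`segments.R`), consensus (`staple.R`), dosimetry (`dosimetry.R`),
  statistics (`stats.R`, `adjust-model.R`, `crossover.R`), cohort
  generator (`cohort.R`), I/O and reporting (`io.R`).
- `src/` — Rcpp kernels: anisotropic Euclidean distance transform,
  point-set nearest neighbours, 3D connected components,
  marching-tetrahedra iso-surfaces.
- `vignettes/automation-bias-methods.Rmd` — the models, conventions,
  generator design, and limitations in detail.
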