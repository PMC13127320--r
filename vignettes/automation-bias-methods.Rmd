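---
title: "Quantifying automation bias in supervised CTV propagation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying automation bias in supervised CTV propagation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

In CBCT-guided online adaptive radiotherapy of bladder cancer, the clinical
target volume (CTV) drawn on the reference image is propagated to the
anatomy of the day by a deformable or rigid registration algorithm, and a
physician reviews and corrects the propagated contour before the plan is
re-optimized. The working assumption of this workflow is that the physician
is an unbiased corrector: whatever error the propagation algorithm commits,
the supervised contour should end up equally close to the true anatomy.

`adaptbias` implements the full analysis needed to test that assumption as
a cross-over experiment: localized test segments are identified where two
propagation algorithms disagree by more than a clinical-relevance threshold,
each physician adjusts each propagated CTV in randomized order, and the
remaining distance of the adjusted segment to a locally registered ground
truth is compared between the worse and the better algorithm. If physicians
corrected perfectly, the worse algorithm's segment would remain worse after
adjustment only about half the time; systematic persistence of the ordering
is automation bias.

## Primary endpoint and statistics

For each test segment the mean distance to agreement against the local
ground truth (`MDA_GT`, mm) is computed before and after adjustment, and
given a sign: positive when the segment lies outside the ground-truth shell
relative to the CTV centre of mass, negative inside (`dMDA_GT`). Per
(segment, physician) pair, the deformable algorithm with the larger
unadjusted `MDA_GT` is the *worse* algorithm; the pairwise comparison is
*positive* when the worse algorithm's adjusted segment still has the
strictly larger absolute `MDA_GT` (ties count against the hypothesis).

The proportion of positive comparisons is tested against 0.5 with the exact
one-sided binomial test at `alpha = 0.025`, designed for an alternative
proportion of 0.65; `exact_binomial_power()` reproduces the design power of
0.928 at n = 130. Confidence intervals are exact Clopper-Pearson intervals
from the beta-quantile representation, and subgroup heterogeneity (segments
above vs at/below the median inter-algorithm MDA) is assessed with Fisher's
exact test under the probability-ordering two-sided definition.

The quantitative adjustment law is a mixed linear model fit by maximum
likelihood with `fit_adjustment_model()`:

* adjusted `dMDA_GT` regressed on unadjusted `dMDA_GT` with **no
  intercept** (an intercept is not supported by this design and is off by
  default, available as an option);
* random intercepts for segment and physician;
* physician-specific slopes, by default as fixed sum-to-zero deviations
  around the global slope, so the `x` coefficient is the unweighted mean of
  the physician slopes; a random-slope variant (`random_slopes = TRUE`) is
  available and is the right choice when the physician panel is itself
  sampled, because the global-slope standard error then includes the
  between-physician slope variance;
* optional fixed effects for algorithm, preceding algorithm (carryover),
  session index (washout), and experience-group slope deltas (the
  least-experienced group is the reference).

A global slope of 1 means the algorithm's error survives supervision
untouched; 0 means perfect correction. Slope heterogeneity across
physicians is tested by a likelihood-ratio test between the models with and
without the slope deviations. Dispersion heterogeneity across
segment-algorithm combinations is tested with
`ansari_bradley_scale_test()`, a k-sample Ansari-Bradley statistic on
median-centred values, with midrank scores; the two-sample case reproduces
`stats::ansari.test` exactly, and an exact permutation p-value is
enumerated for pooled n at or below 12. The chi-square approximation is
crude at such sizes (deviations up to about 0.12 from the exact p in our
checks), which is why the exact path is the default there.

## Geometry on voxel lattices

All geometry is millimetre-aware and honours anisotropic spacing:

* `morph_offset()` expands or contracts a mask by thresholding the exact
  anisotropic Euclidean distance transform (separable lower-envelope
  algorithm in C++). Distances are measured between voxel centres; a
  dilation by r mm of a digitized ball reproduces the analytic volume
  within 2% at 1 mm spacing.
* `extract_surface()` defines the surface as foreground voxels with a
  6-connected background neighbour; the grid boundary counts as
  background. Surfaces are point sets; no meshes are needed for distances.
* `compute_mda()` is the directed mean nearest-neighbour distance
  (segment to ground truth by default — the directionality the endpoint
  description implies; a symmetric mode is available as an option). We
  compute it on the 3D surface; slice-wise 2D variants give slightly
  different values.
* `sign_dmda()` fixes the polarity convention: outward of the ground truth
  (larger radial distance from the CTV centre of mass) is positive. The
  convention is arbitrary but fixed, so regression slopes are comparable.
* `patch_area()` triangulates the 0.5 iso-level of the lightly smoothed
  occupancy (marching tetrahedra) and assigns each triangle to its nearest
  surface voxel, partitioning the total surface area across patches. One
  3-wide box-smoothing pass per axis gives sub-voxel accuracy on smooth
  surfaces (sphere area within about 1%) without rounding sharp edges away.
* `classify_octant()` splits superior/inferior on the z displacement and
  assigns the azimuth by the dominant axis; ties on the 45-degree diagonal
  go to the anterior-posterior class, and a zero z displacement counts as
  inferior. Axis convention throughout: +x left, +y posterior, +z superior,
  origin at the grid corner, all coordinates in mm.

## The test-segment recipe

`identify_test_segments()` implements the rim-Boolean construction: a 1 mm
outer rim of one propagated CTV is intersected with the other CTV
contracted inward by the 5 mm relevance threshold; each connected component
of the intersection marks one deviation site. The test segment collects the
deviating surface's points farther than the threshold from the other
surface, grouped by nearest marker component; the matched patch on the
other surface (and on any third algorithm's surface, and on the ground
truth) is the nearest-point projection. Segments outside 1-25 cm^2 are
discarded. Both offset directions are evaluated, so the recipe is symmetric
in its inputs.

Three discretization details matter on coarse lattices and are part of the
implementation contract: the rim is at least one voxel thick (otherwise a
1 mm rim is empty at 2 mm spacing); marker components closer than the
deviation threshold are merged by single linkage, because the one-voxel
marker shell fragments at coarse resolution; and a literal reading of the
rim construction ("expanded and subtracted from the original") would be
empty, so the outer rim (expanded minus original) is used.

## STAPLE consensus

`staple()` estimates a consensus volume from several readers' masks by
expectation-maximization of the binary model with per-rater sensitivity and
specificity. Initialization is p = q = 0.99, the prior is the scalar mean
foreground fraction (both configurable; the printed results of consensus
analyses do not pin the prior down, so it is exposed), convergence is a
1e-6 tolerance on the largest parameter change with at most 100 iterations,
and the consensus mask thresholds the truth probability at 0.5 with ties
included. The log-likelihood is asserted non-decreasing on every run; the
grouping used in the analysis is one consensus per algorithm across the 13
adjusted volumes.

## Dosimetry

The tissue at risk of underdosage is the inter-shell volume between the
local ground-truth shell and a propagated (or consensus) segment, outside
the generating CTV. `intershell_volume()` rasterizes the shells, closes
their union with an ellipsoidal structuring element (default radii
10 mm — large enough to bridge the deviations the cohort generates, and
configurable since the clinical choice is not published), labels the
enclosed components, and keeps those whose one-voxel dilation touches both
shells, testing adjacency against each shell's exclusive voxels so
coincident shells yield zero volume. Because the shells are zero-volume
surfaces in the continuum, the voxels they occupy are included in the
volume when it is non-empty; without this a 5 mm gap loses two voxel layers
and the analytic shell-sector oracle fails.

`geud()` is the standard power-mean generalized equivalent uniform dose
with the tumour-typical exponent a = -20, computed in log space, with doses
floored at 0.1% before exponentiation. Doses are normalized to the
prescription so the 95% coverage threshold is unitless. The clinical dose
distributions behind the published coverage fractions are not available, so
`coverage_summary()` re-plans a synthetic dose per margin: 100% inside the
margin-expanded CTV with a sigmoid falloff (95% at the target surface,
80-to-20% over a 6 mm penumbra). This supports the qualitative margin
analysis — the below-threshold fraction decreases with margin — but not the
published clinical percentages, which are out of scope.

## The synthetic cohort

The generator is the package's study stand-in, with the cohort structure
the analysis assumes; it is synthetic and labelled as such.

* **Anatomy.** A bladder-like CTV: an ellipsoid with half-axes near
  (36, 33, 31) mm, case-to-case radius jitter of 6%, and a few smooth
  radial lobes (3% amplitude) for irregularity. Grids default to 128^3 at
  1 mm isotropic; tests and the acceptance script use 64^3 at 2 mm — the
  same physical extent at a quarter the resolution, the problem size all
  reported runtimes refer to. A clinical CBCT-like slice spacing is a
  configuration away since all geometry honours anisotropic spacing.
* **Deformation.** The anatomy of the day is the reference CTV under an
  anisotropic bladder-filling scaling (defaults 1.03, 1.05, 1.09); the
  reference contour is its exact pull-back, so forward and inverse
  mappings are analytic and the back-transformation step of the design is
  exact by construction. Landmark-registration noise on the ground truth
  defaults to zero and is exposed as a configuration term.
* **Algorithm errors.** Each deformable arm corrupts the true anatomy with
  Gaussian angular bumps at designated sites: the worse arm with
  amplitudes U(8, 9.5) mm, the better with U(0.5, 1.5) mm, width 0.5 rad,
  outward or inward alternating by segment. These amplitudes are calibrated
  once so every site exceeds the 5 mm relevance threshold and every segment
  lands inside the 1-25 cm^2 area bounds on both the 1 mm and 2 mm
  lattices. The rigid-copy arm places the reference contour unchanged, so
  its error is the filling deformation itself. Thirteen segments are laid
  over ten cases (three cases carry two sites, the second site placed in
  the covered octant farthest from the first); the contour-based arm is the
  worse one for 11 of the 13 segments, and the six octants covered exclude
  the two superior-lateral ones.
* **Physicians.** Thirteen profiles follow the linear under-correction law
  `adjusted = slope * unadjusted + e`, `e ~ N(0, 2.02^2 mm)`, the simplest
  generator whose analysis is exactly the fitted model. The default panel
  is deterministic: slopes anchored at 0.4317 and 1.0332 with panel mean
  exactly 0.7009. Experience groups are assigned by slope rank (the best
  correctors form group A), which gives the qualitative experienced-
  physicians-correct-more pattern; drawn panels
  (`physician_profiles(slope_sd = )`) and explicit slope vectors support
  calibration studies. Heteroscedastic or saturating correction laws are
  deliberately not modelled.
* **Cross-over.** `generate_crossover()` assigns each (physician, case)
  cell one of the six permutations of the three algorithms over the three
  sessions — the balanced Williams-type set for three treatments — cycling
  globally over cells. With 12 physicians the first-order carryover matrix
  is exactly balanced; with 13 the cell count (130) is not divisible by 6
  and the maximum off-diagonal imbalance is 1, the achievable minimum.
  Presentation order within a session is a seeded random permutation.

Every stochastic stage derives an explicit substream seed from the single
run seed; identical seeds reproduce all tables and volumes exactly.

What passing the pipeline's checks does *not* show: the generator has
smooth, star-shaped anatomy, exactly known ground truth, and error bumps of
a single parametric family. Real CBCT anatomy has non-radial deformation,
segmentation noise in the ground-truth registration, and algorithm errors
with richer spatial structure; conclusions about those require clinical
data, not this cohort.

## Record-level simulation vs full geometry

Calibration studies that need hundreds of replicates (slope recovery,
null behaviour of the primary endpoint) use `simulate_records()`, which
draws the unadjusted deviations per segment directly from the configured
magnitude ranges and applies the physician law — the same measurement model
the geometric pipeline produces, without the volumes. The full geometric
path (`generate_study()`) is exercised end to end at paper scale for the
bookkeeping checks: 13 segments, 507 records, 169 primary-endpoint pairs,
a complete 390-presentation schedule. For slope-recovery checks with a
sampled physician panel the random-slope model is fit, since the
fixed-deviation standard error treats the realized panel mean as the
estimand.

## Numerical choices and degenerate inputs

* Ties: better/worse assignment and positivity require strict inequality;
  ties are conservative toward the null. The octant tie on the azimuthal
  diagonal goes to anterior-posterior.
* A contraction that empties a mask warns and returns the empty mask with
  an `emptied` attribute rather than erroring; an empty inter-shell volume
  is a legal zero-volume result.
* A zero mean radial difference with non-zero MDA makes the deviation sign
  undefined; it is set positive and flagged `ambiguous_sign`.
* gEUD at very negative exponents approaches the minimum dose; computation
  in log space keeps a = -1e6 finite.
* Mixed-model fits on noiseless data are degenerate for ML; the fit falls
  back to the fixed-effects least-squares solution (variance components
  zero), which recovers exact slopes to machine precision.
* All condition classes are typed (`adaptbias_geometry_error`,
  `adaptbias_empty_structure_error`, `adaptbias_domain_error`,
  `adaptbias_inconsistent_patch_error`) so callers can discriminate.

## Known limitations

The commercial registration engines, CBCT intensities, DICOM-RT handling,
and the clinical dose distributions are out of scope; the published
clinical dosimetric fractions and the data-dependent medians cannot be
reproduced from synthetic anatomy and are therefore covered by
monotonicity and calibration properties instead. The k-sample scale test
uses a chi-square approximation beyond two groups (no exact k-sample
enumeration), and the 2D slice-wise MDA variant some clinical systems
report is intentionally not implemented.
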