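---
title: "Normative W-score analysis of brain PET on synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative W-score analysis of brain PET on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Carriers of highly penetrant neurodegenerative mutations — the motivating
case is the hexanucleotide repeat expansion in *C9orf72*, the most common
monogenic cause of ALS and frontotemporal dementia — pass through a long
presymptomatic phase in which brain glucose metabolism, measured by FDG-PET,
may already deviate from normal. Detecting such deviations requires a chain
of image analysis steps, each with conventions that materially affect the
result: partial-volume correction for the scanner's limited resolution,
intensity normalization, voxelwise group inference with familywise-error
control, and subject-level normative ("W-score") maps. Because clinical scans
from such cohorts are rarely shareable, `petnorm` pairs the full analysis
chain with a deterministic synthetic phantom generator, so that every stage
can be exercised, calibrated and regression-tested end to end without any
external data.

## The analysis chain and its models

### Partial-volume correction

PET resolution is modeled as an isotropic Gaussian point-spread function
(PSF), default FWHM 5.5 mm (`psf_model()`), converted to a standard
deviation by `fwhm / (2 sqrt(2 ln 2))`. The Müller-Gärtner correction
(`muller_gartner()`) treats each voxel as a mixture of grey-matter (GM)
activity, white-matter (WM) spill-in and GM spill-out:

```
corrected = (pet - wm_activity * blur(wm_prob)) / blur(gm_prob)
```

evaluated only where `gm_prob >= 0.3`; all other voxels are *undefined*
(`NA`), never zero, so downstream masks stay honest. The apparent WM
activity is estimated by `estimate_wm_activity()` as the origin-constrained
least-squares slope of the observed image on the blurred WM probability over
voxels with `wm_prob > 0.95`. The regression is origin-constrained because
deep WM voxels should contain no non-WM signal; this is a design choice (an
intercept would absorb scanner offset but is not identifiable on phantoms
with a single WM compartment) and is deliberately pinned by tests.

For region-level analysis, `region_based_correct()` solves the geometric
transfer matrix (GTM) system: entry (r, s) of the matrix is the mean over
region r of the blurred indicator of region s, and the right-hand side holds
the observed regional means. When tissue maps are available, a WM
"background" compartment (`wm_prob >= 0.5` outside the atlas) absorbs spill
from unlabelled tissue. A transfer matrix with condition number above 1e8 is
refused with an error rather than silently solved.

### Masking, normalization, smoothing

The analysis mask (`make_analysis_mask()`) is the pooled mean GM probability
thresholded strictly above 0.1, minus named excluded regions (the occipital
lobe by default — mirroring designs in which uncontrolled visual input at
tracer injection makes occipital uptake uninterpretable). The pooled
(all-subject) mean map is used rather than a control-only mean; with both
groups on one template the difference is negligible and the pooled map is
the one a comparative morphometry pipeline produces.

`proportional_normalize()` divides by the in-mask mean, so the normalized
in-mask mean is exactly 1. We deliberately use 1 rather than the grand-mean-50
convention of some packages: every downstream statistic is scale-invariant,
so the choice is cosmetic, and 1 keeps percent differences directly
readable. `suvr()` offers reference-region (cerebellar) scaling as the
alternative. Smoothing (`smooth_volume()`, default 8 mm FWHM) uses
*normalized convolution* inside the mask: constants are preserved, undefined
voxels contribute nothing, and no intensity ever leaks from excluded regions
into the mask (an impulse placed in the occipital label stays there).
Outside any mask, plain separable Gaussian convolution with whole-sample
reflection at the grid edges is used.

### Group inference

`fit_glm()` runs voxelwise ordinary least squares with an intercept, a
carrier indicator, and mean-centered age (plus total intracranial volume for
the volumetric analysis). Hypotheses are one-sided (`make_design()`
direction `"hypo"` tests control > carrier). Suprathreshold voxels at the
height threshold p < 0.001 are grouped into clusters under 18-connectivity
(faces + edges, the convention of mainstream neuroimaging packages; 6 and 26
are available) and clusters smaller than 150 voxels are dropped.

Cluster-level familywise error is controlled by permutation rather than
random-field theory: `cluster_fwe()` uses Freedman–Lane residualization
(reduced-model residuals are row-permuted and the reduced fit added back)
and compares each observed cluster's size with the permutation distribution
of the *maximal* suprathreshold cluster size. Corrected p values use add-one
smoothing, `(1 + #{perm max >= size}) / (1 + n_perm)`, which keeps the test
valid at any number of permutations; the permutation seed is a mandatory
argument and is recorded in the output provenance. Random-field theory was
not implemented because its assumptions (stationary smoothness, high
thresholds) are exactly what a small phantom grid violates, whereas the
permutation route is assumption-light and directly testable for calibration.

Each reported cluster carries a percent group difference,
`100 (control - carrier) / control`, measured by default on the normalized
*unsmoothed* (partial-volume-corrected) images rather than the smoothed GLM
inputs: smoothing dilutes an effect across cluster borders, and the
percent difference is meant to report the magnitude of the underlying
signal, not of its smoothed shadow.

### W-score maps

`fit_normative()` regresses intensity on age per voxel over the controls;
the residual SD uses the model degrees of freedom, n − 2 (the n convention
would shrink W slightly; the null-calibration test pins the behavior).
A subject's W-map is

```
W = (raw - (intercept + slope * age)) / resid_sd
```

a covariate-adjusted z-score. Abnormality thresholds are *inclusive*:
hypometabolism flags `W <= -1.96`, hypermetabolism `W >= +1.96`, the value
1.96 being the two-sided 2.5th percentile of the standard normal
(`central_mass(1.96)` = 0.95). Binarized maps are summed into frequency maps
(`frequency_map()`), averaged into mean maps (`mean_wmap()`), and counted by
atlas region (`region_supra_counts()`, where "a region is affected" means
any suprathreshold voxel in it — a minimum-voxel-count variant is a
parameter away but the any-voxel rule is the default). A normative fit whose
in-mask residual SD is zero (possible only on noise-free synthetic data) is
refused at fit time unless `allow_zero_sd = TRUE`, so W-maps can never
divide by zero.

### Regional confirmation and clinical statistics

`region_table()` + `group_compare_regions()` run the volume-of-interest
confirmation: per region, a linear model of the (GTM-corrected) regional
mean on group and age, tested one-sidedly, with Benjamini–Hochberg step-up
control (`benjamini_hochberg()`) across regions.

Clinical comparisons follow cohort-table conventions: Pearson chi-square
*without* continuity correction on 2x2 counts (this convention is pinned by
reproducing published table statistics exactly), and a Mann–Whitney U from
mid-rank sums — exact enumeration when both samples have at most 8
observations, otherwise a tie-corrected normal approximation with continuity
correction. The exact and approximate branches agree to within 0.01 at the
boundary for continuous data; heavily tied lattices can differ by slightly
more, which is a known property of the lattice, not of the implementation.
Neurofilament concentrations are flagged against *strict* diagnostic cutoffs
(NfL 1227 pg/mL, pNfH 750 pg/mL — a value exactly at the cutoff does not
"surpass" it), and cognitive subdomain scores are abnormal strictly below
the normative 5th percentile, `mean - 1.6449 sd`, with the normative table
supplied as data (`cutoff_config()`, `classify_ecas()`).

## The phantom generator

`phantom_spec()` + `build_template()` + `simulate_cohort()` define the
synthetic world. The template is an idealized head: an ellipsoidal cerebrum
with a cortical GM shell over a WM core, ventricular and peripheral CSF, a
separate cerebellum, and 14 named atlas parcels. Deep-GM structures
(thalami, insulae) are GM islands embedded in WM — anatomically faithful for
subcortical grey, and consequential: the analysis mask (GM > 0.1) bounds
detected clusters at the structure borders, so cluster-wise percent
differences reflect the injected effect rather than smoothing spill.
Cortical parcels are nearest-prototype sectors of the shell, with prototype
positions jittered by the seed.

Subject uptake is linear in age per voxel,
`(intercept + slope * age) * (gm_prob + wm_uptake_fraction * wm_prob)`, with
defaults 100 a.u. at age 0, −0.4 a.u./year over ages 30–65, and a WM
compartment at 0.25 of the GM level (the ~4:1 grey:white FDG ratio). Without
the WM term the Müller-Gärtner WM-spill-in correction would be vacuous on
cohort images; tests of the pure GM age line set `wm_uptake_fraction = 0`.
Carrier lesions multiply named regions: defaults are −25% metabolic in
thalami and insulae, +6% in the peri-Rolandic parcels, and −20% GM volume in
thalami and insulae — magnitudes chosen once, inside the ranges reported for
presymptomatic carriers, not fitted to anything. The noise-free image is
blurred by the acquisition PSF (5.5 mm) *before* i.i.d. Gaussian voxel noise
is added (default SD 6 a.u., roughly 8–10% of the GM signal): the noise
models post-reconstruction variability, and this ordering keeps PSF
inversion testable. GM-volume maps scale the GM prior by each subject's
TIV ratio, apply atrophy effects the same way, and are blurred at 4 mm (an
MRI-resolution stand-in).

Clinical covariates are drawn per group: female fraction (0.71 carriers /
0.48 controls), TIV ~ N(1.45e6, 1.2e5) mm³, lognormal CSF neurofilaments
with an elevated NfL mixture component hitting ~19% of carriers (centered
safely above the 1227 pg/mL cutoff), cognitive subdomain scores from the
normative distributions with a 2.2-SD executive/fluency deficit in ~29% of
carriers, and upper-motor-neuron signs in 59% of carriers.

**What the phantoms do not emulate:** cortical folding, nonstationary and
spatially correlated between-subject variability, registration error,
scanner nonuniformity, and any longitudinal structure. Passing tests on
phantoms therefore demonstrate that the *algorithms* are correct and
calibrated under their stated assumptions — they do not certify performance
on real scans, where between-subject variance is spatially structured and
effect magnitudes are unknown.

## Numerical choices

- Gaussian blur: separable convolution matrices with whole-sample
  reflection; kernel truncated at 4 sigma; `fwhm = 0` is the exact identity.
- Undefined voxels are `NA` end to end; smoothing and statistics ignore
  them; they are counted in the PVC report rather than imputed.
- Strict vs inclusive boundaries are deliberate and tested: mask threshold
  strict (`> 0.1`), W thresholds inclusive (`<= -1.96`, `>= 1.96`),
  neurofilament cutoffs strict (`> 1227`), cognitive percentile strict
  (`< mean - 1.6449 sd`).
- The GTM solve refuses condition numbers above 1e8 (configurable) and
  reports the number; degenerate Müller-Gärtner denominators (blurred GM
  below 1e-3) mark voxels undefined and are counted.
- Permutation p values use add-one smoothing and a mandatory seed; with
  n_perm = 500 the finest achievable p is 1/501.
- A normative residual SD is treated as zero when below 1e-8 of the mean
  absolute intensity, guarding the division in W.

## Problem sizes used by the test suite

The suite exercises the full default grid (48 x 56 x 48 at 3 mm, ~28,000
mask voxels, 25 + 17 subjects) for the end-to-end lesion-recovery check, and
reduced grids elsewhere, chosen as the smallest worlds in which the property
under test is identifiable: 24 x 28 x 24 (~4,700 mask voxels, 10 + 10
subjects, 200 null cohorts x 500 permutations) for the familywise-error
calibration, and 36 x 42 x 36 (~13,000 mask voxels, 500 controls + 200 held
out nulls) for the W-score null calibration. These sizes are the package's
own choices balancing Monte-Carlo resolution against a test suite a
developer will actually run.

## Known limitations

- The phantom's i.i.d. voxel noise understates the spatially correlated
  between-subject variability of real cohorts; real-data t statistics will
  be far smaller at equal effect size than phantom ones.
- The Müller-Gärtner WM-activity regression assumes a single WM activity
  level; focal WM pathology would bias it.
- Freedman–Lane permutation assumes exchangeable subjects under the reduced
  model; strong heteroscedasticity between groups would require a Welch-type
  statistic, which is not implemented.
- The exact Mann–Whitney branch enumerates all assignments and is limited to
  both samples having at most 8 observations by design.
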