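---
title: "Decoding imagined motion direction: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding imagined motion direction: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionmvpa)
```

## The problem this package addresses

When a person imagines dots drifting in a particular direction — without any
visual stimulus on screen — the pattern of activity across voxels in early
visual cortex can carry information about *which* direction is being
imagined. Detecting that information requires a multi-voxel pattern analysis
(MVPA): single-voxel amplitudes are too weak and too unspecific, but a
linear classifier reading hundreds of voxels jointly can decode the imagined
direction from single trials. This package implements the complete analysis
chain for such an experiment — from paradigm simulation through
cross-validated decoding, permutation inference, searchlight information
mapping, univariate preference maps, and eye-movement confound controls —
as tested, reproducible R code.

Because no raw 7 T data accompany the design, the package ships a
first-class synthetic-data generator with known ground truth. Every
downstream stage is validated against that ground truth, so the test suite
demonstrates *recovery* (implanted signals are found) and *calibration*
(absent signals are not).

## The experimental design being simulated

The simulated paradigm follows a blocked four-direction imagery experiment:

* 4 runs per session, 10 blocks per run, 4 trials per block — one trial per
  direction condition in random order within each block, giving 160 trials
  and exactly 40 per condition;
* trial durations of 6 or 8 s; an initial 12 s rest per run; inter-block
  rests of 8, 10, or 12 s (the post-block rating period of the real task is
  folded into the rest, since it contributes no modeled signal);
* TR = 2 s, nominal 1.1 mm isotropic voxels.

The design does not state how the 6 s / 8 s durations or the rest jitters
were assigned, so the generator draws them equiprobably and seeded — the
stated value sets without invented structure. All durations are integer
multiples of the TR, so onsets always sit on the volume grid.

## Forward model

Each voxel's time course is

$$y(t) = \beta_0 + \sum_{c=1}^{4} a_{c,v}\, (u_c * h)(t) + d(t) + \varepsilon(t)$$

where $u_c$ is the condition-$c$ trial boxcar, $h$ the canonical two-gamma
hemodynamic response (peak delay 6 s, undershoot delay 16 s, dispersions
1 s, peak:undershoot 6, max-normalized; empirical peak near 5 s), $a_{c,v}$
the ground-truth amplitude of voxel $v$ for condition $c$, $d(t)$ a
one-cycle-per-run cosine drift, and $\varepsilon$ iid Gaussian noise. The
drift is deliberately placed *below* the high-pass filter band (two cycles
per run) so the filtering stage has something real to remove. The
convolution is evaluated at TR resolution without oversampling, which is
exact here because all paradigm times are TR multiples.

What the generator does **not** emulate: spatial noise correlations,
physiological noise spectra, motion, distortion, or any columnar spatial
structure. Passing tests therefore demonstrate the correctness and
calibration of the *analysis machinery*, not performance claims about real
7 T data.

## Preprocessing

The stage order is fixed: high-pass filter, then run-wise z-scoring, then
trial feature extraction.

* **High-pass filtering** regresses out a GLM Fourier basis per run —
  intercept, linear trend, and sine/cosine pairs at 1 and 2 cycles per run —
  and restores the run mean.
* **Z-scoring** standardizes each voxel within each run using the
  *population* (denominator $N$) standard deviation; the convention had to
  be fixed one way, it is flagged explicitly so tests can be exact, and
  constant voxels map to zeros with a flag rather than NaN.
* **Feature extraction** averages, per trial and voxel, the volumes whose
  onset-relative acquisition time lies in the half-open window
  $[4, 10)$ s. At TR = 2 s this is exactly the 3 volumes at 4, 6, and 8 s —
  the half-open convention is the one that uniquely yields 3 TRs. Off-grid
  onsets (impossible under the default paradigm) are rounded to the nearest
  volume as a degenerate-input safety net.

## The decoder

`mvpa_decode()` is the package's central fit. Within each leave-one-run-out
fold:

1. one-way ANOVA F scores (between/within class variance ratio) are
   computed per voxel *on the training trials only*;
2. the top `k` voxels are kept (default 1000, the design's value; ties at
   the cutoff break towards the lower voxel index, infinite F — zero
   within-class variance — sorts above all finite scores);
3. six binary soft-margin linear SVMs (one per class pair, default
   C = 1 since the design names only a linear maximum-margin classifier)
   are trained, and held-out trials are predicted by majority vote, ties
   towards the lowest class label.

The fold-wise selection is the no-leakage property the tests verify
explicitly: corrupting held-out labels cannot change the selected voxels.

**Permutation inference.** The scrambled-label null re-runs the *entire*
analysis — including fold-wise feature selection — `n_perm` times (default
1000) with labels permuted uniformly over all trials (class counts
preserved). Whether the original analysis scrambled within runs is not
stated; global permutation matches an exchangeable null and a within-run
mode is available via `perm_scheme`. The p-value uses the add-one rule
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$, which avoids
$p = 0$ and is standard for Monte-Carlo tests. The real-data precondition
that every run contain every class is relaxed for the scrambled reruns
(a permutation may leave a held-out run without some class; training folds
still require all classes).

## Group statistics

The group stage uses exact, tie-aware non-parametric tests because the
target sample size (12 subjects) makes asymptotics dubious:

* **Wilcoxon signed-rank** (real accuracy vs. each subject's mean null
  accuracy): zero differences dropped, midranks for ties, W = smaller
  signed-rank sum, exact two-sided p by enumeration of sign assignments
  (computed by generating-function convolution; identical to literal
  enumeration) for n ≤ 25.
* **Mann-Whitney U** between the two direction groups: exact enumeration
  over group assignments when feasible.
* **Spearman + FDR**: rank correlations of mean accuracy with the three
  questionnaire scales, Benjamini-Hochberg adjusted across scales (the FDR
  variant is not named in the design; BH is the standard choice).

`stats::wilcox.test` cannot produce exact p-values under ties, which is why
the enumeration versions are authored here; the tests cross-check them
against `wilcox.test` in the tie-free exact regime and against the normal
approximation at larger n. Note that for 12 subjects with uniformly
positive differences, W = 0 has an exact two-sided p of
$2/2^{12} \approx 0.0005$.

## Searchlight mapping

A sphere of radius 4 voxels (Euclidean norm, inclusive boundary — the
convention that yields exactly 257 voxels) is moved over every voxel of a
ribbon mask. Only the *center* must lie in the ribbon; members are clipped
to the volume but not masked (a strict mode masks members too). Per center
the full decoder runs with **no** feature selection and **no** permutation
test; significance comes instead from a Pearson chi-square test of the
pooled confusion matrix (df fixed at 9 for the 4-class design; zero-expected
cells contribute zero, which matters when a class is never predicted), with
BH-FDR across centers. Whether the original analysis pooled the confusion
over folds or tested per fold is unstated; pooling is assumed. The
anatomical ribbon construction (−1 mm to +3 mm from the gray/white boundary)
is out of scope; any mask serves. The surface cluster-size threshold of the
original design has no volumetric counterpart here and is omitted (an
optional connected-component filter was considered and left out as default
off, i.e. not implemented — maps are exported unfiltered).

## Univariate analysis and preference maps

A voxel-wise OLS GLM with HRF-convolved condition predictors, per-run
intercepts and optional per-run linear drift supports one-vs-all contrasts
(+1 on the tested condition, −1/3 on each other — zero-sum, so a
non-selective voxel scores t ≈ 0). T-maps are thresholded at q < 0.05
(BH-FDR across voxels). The preference map labels each voxel, within the
searchlight significance mask, with the argmax of the four contrast
t-values (ties towards the lowest label). A single shared GLM feeds both
the thresholded t-maps and the preference map.

## Eye-movement controls

* **Blink rejection**: per trial, samples with pupil aspect ratio outside
  mean ± 2 SD are discarded ("± 2SD" read literally), along with dropout
  samples.
* **Saccade detection**: the velocity-threshold approach standard for
  microsaccade work — 5-sample moving-window velocities, robust
  (median-based) SD per axis, elliptic criterion at λ = 6 sustained for
  ≥ 3 samples. λ, the minimum duration, and the 60 Hz default sampling rate
  are the canonical values for this detector class and are configurable;
  the original recording parameters are not reported.
* **Circular statistics**: Fisher's common-median test across imagined
  directions and the Jammalamadaka-SenGupta circular-circular correlation
  with the imagined direction, both authored here (no installed package
  provides them) and validated by calibration simulations and rotation
  invariance.
* **Gaze ellipses**: a minimum-volume enclosing ellipse per trial via
  Khachiyan's algorithm (tolerance 1e-4, then inflated by at most the
  convergence slack so every point is strictly enclosed). Ellipse rotation
  is an *axial* quantity (a line, not a direction), so rotations are doubled
  before the circular tests and results reported on the doubled scale.

## Numerical choices and degenerate inputs

* All randomness flows from one master seed fanned out to named substreams
  (events, noise, gaze, permutations), so stages are independently
  reproducible and the whole bundle is deterministic for a fixed seed.
* Vote ties → lowest class label; F ties at the selection cutoff → lowest
  voxel index; preference ties → lowest condition label. All documented,
  all deterministic.
* Constant voxels: z-scoring maps them to zeros and flags them; zero
  residual variance in the GLM flags infinite t rather than NaN.
* The permutation null's 95th percentile uses R's default quantile
  definition (type 7).
* `paradigm_spec()` accepts a single run (useful for event generation and
  gaze work); everything that needs leave-one-run-out — the decoder and the
  pipeline validator — enforces at least two runs.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: direct
convolution for the forward model and design matrices, brute-force lattice
enumeration for sphere counts and mask dilation, literal enumeration for
the exact tests, a coarse grid search for the enclosing ellipse, and
`stats::aov` / `chisq.test` / `wilcox.test` where base R offers an
independent route. Calibration suites run the full pipeline on
label-uninformative data: 50 default-paradigm datasets for the
chance-level check (grand mean accuracy within the pooled binomial 95%
interval of 25%) and 100 reduced datasets (4 blocks per run, 27-voxel ROI,
99 permutations) for the rejection-rate check at α = 0.05. Signal-recovery
suites implant direction-tuned voxels at amplitudes well above the noise
and require > 90% decoding accuracy, the minimal possible permutation
p-value, searchlight peak localization within one radius, and ≥ 90% correct
preference labels at significant implanted voxels. These sizes are the
package's choices for a desk-scale demonstration; the same functions run
unchanged at the full design scale (1000 selected voxels, 1000
permutations, radius-4 searchlight over a cortical ribbon).

Cross-validated accuracy on truly uninformative data sits very slightly
*below* the nominal 25% on average — the familiar pessimistic bias of
cross-validation under the null, caused by the anti-correlation of training
and test class proportions within folds — which is why calibration is
checked against a binomial interval rather than an exact equality.

## Known limitations

* The simulator's noise is white in space and time; real BOLD noise is
  neither, so absolute accuracies on synthetic data do not predict real
  data performance.
* No prewhitening/autocorrelation modeling in the GLM; no slice-timing or
  motion correction anywhere (out of scope by design).
* The searchlight is volumetric; no surface projection is provided.
* Exact group tests are exponential-support enumerations intended for
  small samples (n ≤ 25 pairs); larger samples switch to the tie-corrected
  normal approximation.
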