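---
title: "Cross-sectional ADC profiling of ring-enhancing lesions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-sectional ADC profiling of ring-enhancing lesions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Ring-enhancing lesions (RELs) — glioblastoma (GBM) and brain abscess being
the two most consequential — look deceptively similar on conventional MRI:
a core, a contrast-enhancing ring, and surrounding vasogenic edema. Their
diffusion signatures differ, however: viscous pus restricts water diffusion
(low apparent diffusion coefficient, ADC), while necrotic tumour core
diffuses freely (high ADC). Absolute ADC values in hand-drawn regions of
interest are hard to compare across scanners and studies; this package
instead analyses the *dynamics* of ADC along a line of interest (LOI) drawn
from normal-looking tissue, across the edema and the enhancing ring, into
the lesion core.

The sampled 1-D profile is segmented at six landmarks:

* **A** — onset of the edema-related ADC elevation,
* **B** — start of the elevated edema plateau (plateau 1),
* **C** — end of plateau 1, where ADC starts to fall toward the ring,
* **D** — the ring minimum (strongest diffusion restriction),
* **E** — start of the core plateau (plateau 2),
* **F** — the profile end at the lesion center.

Each profile is summarised by two-point gradients over A–B, C–D and D–E
(`grad_E_rise`, `grad_E_fall`, `grad_T_rise`, in ADC units per pixel,
signed) and the mean / sample SD / median of each plateau. The nine-entry
vector (or the seven-predictor subset that drops the two means) feeds
nonparametric group tests and two classifiers: k-nearest neighbours and a
soft-margin SVM with Gaussian kernel, both on features standardized to mean
0 / variance 1 using training-set statistics only.

ADC values are kept in "paper units", the magnitudes printed on clinical
maps (10^-6 mm^2/s physically); nothing in the pipeline converts units.

## Assumptions the method makes

* A single representative slice suffices (the workflow is deliberately 2-D).
* Every LOI crosses all compartments in order; profiles are monotone-rise /
  plateau / fall / minimum / rise / plateau shaped. Lesions that lack a
  markable edema plateau will fail landmark detection, by design.
* Lines from the same patient are not independent; all subject-level
  decisions (train/test split, CV folds) therefore operate on subjects, and
  all five LOIs of a patient travel together.

## Sampling and interpolation

`sample_loi()` samples the map at arc lengths `0, step, …, ||F − A||`
(endpoint always included; default step 1 px, matching the one-pixel-wide
line the features assume) and interpolates bilinearly from the four
surrounding pixel centers. Coordinates are 0-based `(row, col)` with pixel
centers at integer positions. Out-of-bounds samples raise an error rather
than clamping — silent clamping would corrupt gradients. A perpendicular
band average (`band_px`) is available but off by default: the plain
interpolated ray is the simplest faithful reading of a one-pixel-wide line.

Bilinear interpolation is exact for fields that are linear in each
coordinate. On the radially symmetric phantom this makes axis-aligned rays
interpolation-exact, while oblique rays carry an angle-dependent error that
concentrates near slope kinks (up to tens of ADC units right at the ring
minimum, where the radial slope flips sign by ~100 units/px). Tests
therefore check exact feature recovery on grid-aligned rays and ±1-sample
landmark recovery on oblique ones; the analytic per-LOI ground-truth
profiles returned by `generate_map()` are identical across angles by
construction.

## Automatic landmark detection

In clinical use the landmarks are expert-placed (and manual annotations
always override the detector). The automatic detector is a transparent
heuristic for synthetic data and pre-annotation:

1. **Coarse stage.** Slopes of a moving-average-smoothed profile
   (window 5) are estimated by central differences over half the window.
   Threshold crossings (`rise_slope_threshold` 15, `plateau_slope_threshold`
   8 ADC units/px) are grouped into runs; the edema-to-ring fall is the run
   with the largest total descent, the edema rise the largest ascent before
   it, the core rise (if any) the largest ascent after it. Amplitude
   selection, rather than first occurrence, is what makes the stage robust
   to spurious threshold crossings under noise.
2. **Refinement.** Background, plateau-1 and plateau-2 levels are estimated
   as raw-sample medians away from the transitions; least-squares lines are
   fitted to ramp interiors, and A, B, C, E are placed at line/level
   intersections. Threshold runs overshoot the true ramp by a
   slope-dependent smear (the slope estimator has finite support), so the
   fit searches left/right trims and accepts the largest interior that is
   collinear to machine precision — on noise-free piecewise-linear profiles
   this recovers the construction breakpoints *exactly*, which is the
   property the recovery tests pin down. A naive "first index where the
   slope falls below threshold" rule would instead carry a systematic
   ~2-sample lag. Under noise, where no collinear interior exists, the fit
   falls back to a trimmed least-squares line (at least 5 points) and, if
   that degenerates, to the run-amplitude slope.
3. **D** is the earliest raw-value argmin inside the detected fall region
   (plus a two-sample margin): the ring minimum is a raw-profile extremum,
   so no smoothing is applied to it. **E** for lesions with a weak core
   rise (abscess-like cores barely above the ring) falls back to a short
   line fit from D toward the core plateau level.

Degenerate inputs fail loudly: a flat profile has no rise and fails at
point A; a profile with no descent fails at C; ordering violations abort
rather than silently reordering. Detection is deterministic, equivariant to
adding a constant to all values, and approximately equivariant to
upsampling.

D-localisation accuracy under noise depends on the local geometry: with the
default GBM phantom (fall ~60, core rise ~75 ADC/px against noise SD 50)
the ring minimum is recovered within ±2 samples in well over 95% of
profiles; for abscess-like profiles whose core sits barely above the ring
the right flank of the "V" is nearly flat (~6 ADC/px) and pinning D to ±2
samples is intrinsically ill-posed at that signal-to-noise — detection
still succeeds, but the argmin wanders a few samples.

## The synthetic phantom

No public dataset accompanies the clinical study this design emulates, so
the phantom module is first-class, tested code. A lesion profile is
piecewise linear: background plateau (default 725, the normal parenchyma
range), linear rise to the edema plateau, fall to the ring minimum, rise to
the core plateau. Defaults (GBM: edema 1400, ring 600, core 1900; abscess:
edema 1150, ring 550, core 650; noise SD 50; subject-level level jitter SD
40) are declared configuration: levels were chosen once so that the class
ordering of the plateau medians matches the reported clinical pattern and
the background matches the normal range; the magnitudes are otherwise free.
Noise is additive Gaussian truncated at zero (the simplest model consistent
with non-negative ADC). Transitions may optionally be smoothed by a moving
average (`transition_smoothness`), off by default so that ground-truth
gradients stay analytic. The thin enhancing ring is represented only by the
D minimum — on clinical ADC maps it is too thin to carry a plateau of its
own.

**Why cohort gradients are drawn, not derived.** The clinical comparison
found class differences in the plateau medians but not in the gradients.
A gradient is Δlevel/length, so with fixed ramp lengths and class-dependent
levels the gradients would separate the classes mechanically. The cohort
generator therefore draws the three ramp slopes per LOI from class-shared
truncated normal distributions (means 45 / 60 / 50 ADC units/px, SDs 6 / 8
/ 8) and derives integer ramp lengths as `round(Δ/slope)`; the realized
plateau levels absorb the rounding, so the noise-free gradient of every
ramp equals the drawn slope exactly for both classes. The ring-to-core span
additionally has a floor of 6 samples: a two-point gradient over a very
short span would inherit a large, class-specific noise variance and leak
class information through a feature that is drawn class-independently.
A consequence is that realized abscess cores sit at
`ring + 6 × slope ≈ 850` rather than the nominal 650; the class ordering
and separation of the core medians are unaffected.

What the phantom does **not** emulate: brain anatomy, partial-volume and
coil-profile effects, Rician noise statistics, heterogeneous or
non-radially-symmetric lesions, and radiologist placement variability.
Passing the recovery and pattern tests therefore demonstrates internal
consistency of the pipeline, not clinical performance.

## Group statistics

The feature comparison mirrors the clinical analysis: a Shapiro–Wilk
normality screen first (it only gates reporting — the pipeline always
proceeds nonparametrically), then two-sided tests at α = 0.05 per
comparison: Wilcoxon rank-sum for the plateau medians and SDs, and
Kruskal–Wallis for each gradient (for two groups it is the square of the
rank-sum z, which a test verifies). "Wilcoxon" is the two-sample rank-sum
form — the groups are independent patients, not pairs. The rank-sum test
uses exact enumeration when `n1 + n2 ≤ 12` and the pooled sample is
tie-free, otherwise the tie-corrected normal approximation without
continuity correction. No multiple-testing correction is applied by default
(per-comparison reporting, as in the clinical analysis); Holm is available.

Because the five LOIs of a subject share that subject's level jitter,
line-level tests on medians are not iid — this mirrors the clinical design
(200 lines from 40 patients) and is why the null-calibration test draws one
line per subject.

## Classification

* Splits: subject-level, stratified by class, rounded to the nearest
  integer per class (40 subjects at 75% → 30 training subjects → 150/50
  lines).
* Standardization: training mean / sample SD (n−1 throughout, consistent
  with the plateau SD features); zero-variance features are dropped with a
  warning; transformed matrices carry a flag so a second standardization is
  rejected rather than silently double-scaled.
* k-NN: Euclidean, default k = 5 (odd, reducing vote ties; k is not
  clinically prescribed and a CV grid {1,3,5,7,9} is available). Vote ties
  break to the single nearest neighbour's label, distance ties to the lower
  training index — fully deterministic.
* SVM: Gaussian kernel `exp(−γ‖x−x′‖²)`, soft margin; defaults C = 1,
  γ = 1/(n_features × mean feature variance). The fitted object exposes the
  dual quantities and is checked against `0 ≤ αᵢ ≤ C` and `Σ αᵢyᵢ = 0`
  (tolerance 1e-6).
* Cross-validation: five folds, grouped by subject and stratified by class
  (the fold construction is not clinically prescribed; grouping follows
  from the subject-level split), standardizer refit inside each fold,
  pooled confusion matrix as the sum of fold matrices.
* Metrics: `Acc = (TP+TN)/total`, `TPR = TP/(TP+FN)`, and `FNR` computed as
  `1 − TPR` so the complementarity identity holds exactly in floating
  point. The positive class defaults to ABSCESS — the clinically urgent
  diagnosis.
* `tune_model()` walks an ordered hyperparameter grid by CV accuracy and
  stops after `patience` non-improvements — a cross-validation analogue of
  early stopping for these non-iterative learners.

## Reproducibility and problem sizes

All randomness flows from one root seed through named substreams (phantom,
split, CV), so a config reproduces every numeric output byte-for-byte; the
pipeline writes a manifest with the seed, config hash and versions. The
validation suite uses cohorts of 26 + 14 subjects × 5 LOIs (200 lines,
the clinical design), 20-seed sweeps for the statistical-pattern and
classification-recovery properties, 100-profile Monte-Carlo runs for the
noisy detector, and 2000 null replicates for rank-sum calibration — sizes
chosen to give stable Monte-Carlo estimates while keeping the whole suite
interactive.

## Known limitations

* Single-slice, straight-line analysis; no volumetry, no curved LOIs.
* DICOM series input is not supported; convert to NIfTI first.
* The landmark detector is a stand-in for expert placement; its thresholds
  are tuned to the phantom's geometry, and profiles that violate the
  canonical shape fail rather than adapt.
* Held-out accuracy on the default phantom is near-perfect because the
  default class separation is generous relative to the noise; it is a
  recovery check on the pipeline, not an estimate of clinical accuracy.
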