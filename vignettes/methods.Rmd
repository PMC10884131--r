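---
title: "Methods: simulating, correcting and quantifying attenuation artifacts in myocardial perfusion SPECT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, correcting and quantifying attenuation artifacts in myocardial perfusion SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(acspect)
```

## The problem

Non-attenuation-corrected myocardial perfusion SPECT systematically
under-reads the inferior wall of the left ventricle: photons emitted there
traverse more tissue, and the count depression mimics a real perfusion
defect. CT-based attenuation correction fixes this but requires a hybrid
scanner and extra dose. `acspect` implements a CT-less alternative: learn a
mapping from non-corrected SPECT short-axis images to "PET-like" images,
with 13N-ammonia PET (which is CT-corrected and quantitatively reliable)
defining the target domain, then verify on AHA 17-segment quantification
that the inferior-wall bias present in SPECT is absent in the translated
images (`spect_spt`).

Because clinical SPECT/PET pairs cannot be redistributed, the package is
organized around a synthetic cohort with known ground truth. Every module
is usable on real short-axis stacks with the same file conventions.

## The synthetic world

`generate_patient_pair()` rasterizes one anatomy at the two acquisition
geometries: SPECT at 2.4 mm pixels / 2.4 mm slices and PET at 1.6 mm / 1.6
mm, both on square matrices (clinical default 128, desk default 64). The
myocardium is an annulus whose endo- and epicardial radii taper linearly
toward the apex (epicardial 24 mm to 60% of that, endocardial 17 mm to
25%); the apex slab is a filled disc. The default LV length of 38.4 mm
gives 16 SPECT and 24 PET slices, reproducing the unequal slice counts the
pairing chain must handle.

Three overlays define pathology and physics:

* **Defects** (`defect_spec`): a set of AHA segments and a fractional
  severity; voxels of those (slab, sector) wedges are multiplied by
  `1 - severity`. The rasterized wedge is dilated by each pixel's angular
  footprint (`atan(1.45 / radius)`). This is deliberate: the segment
  quantifier takes radial *maxima* of bilinearly interpolated samples, so
  an undilated wedge lets boundary rays latch onto bright pixels of the
  neighboring sector and biases the defected segment's value upward. With
  the dilation, the defected segment reproduces
  `baseline * (1 - severity)` exactly (a tested invariant); the price is a
  small conservative bias (a few uptake units) in the two adjacent
  sectors, which the maximum-statistic largely rescues.
* **Attenuation** (`attenuation_spec`): a smooth multiplicative field,
  separable into an angular raised-cosine bump times a per-slab
  multiplier. The default points at the inferior wall (270 degrees) with a
  120-degree width; the per-voxel factor lies in `[min_factor, 1]`. The
  literature reports no quantitative magnitude for the inferior artifact,
  so the default `min_factor = 0.8` (a 20% maximal depression, ~16%
  averaged over the inferior sector) is a simulation choice, not a
  measured value.
* **Noise**: a Poisson-like perturbation, `noise_scale * sqrt(intensity)`
  times a unit-variance *spatially correlated* Gaussian field (correlation
  sigma 4 mm). Reconstruction-filtered emission images have smooth noise;
  voxel-white noise would inflate the radial-maximum statistic differently
  in the two geometries and bias every segment comparison. The default
  `noise_scale = 0.5` gives roughly 5% relative noise at baseline uptake,
  typical of filtered clinical reconstructions. These were fixed on
  realism grounds before any acceptance measurement and are not tuned.

What the generator does **not** emulate: anatomically realistic torsos
(no XCAT-class organs), projection-domain physics, scatter, collimator
response, or patient motion. A green parameter-recovery test therefore
establishes that the *pipeline* can learn and quantify a smooth
inferior-wall depression — not that the model corrects clinical attenuation.

## Angular convention

The package fixes one global convention (the source description leaves it
open, and its two natural readings conflict): on a standard short-axis
display (anterior up, septum left), the anatomical angle increases
counterclockwise with the anterior wall at 90 degrees and the inferior
wall at 270. Segment #1 (basal anterior) spans [60, 120); basal and mid
rings are six 60-degree sectors, the apical ring four 90-degree sectors,
the apex slab maps entirely to segment #17. `aha_segment_of()` is the
single source of truth, and the attenuation default `peak_direction_deg =
270` aims at the inferior wall in this convention.

## The pairing chain

`preprocess_pair()` reproduces the dataset-matching steps in order:

1. `align_slice_counts()`: the PET stack is reduced to the SPECT slice
   count by nearest-neighbor selection along the long axis (slab centers
   measured from the basal-most slice; intensities are never
   interpolated).
2. `resample_and_crop()`: SPECT slices are magnified by 2.4/1.6 = 1.5
   (bilinear; the enlargement kernel is unstated in the source, and the
   choice is logged in the resample record) and center-cropped back to the
   PET matrix.
3. `to_uint8()`: per-stack linear quantization with the maximum at 255.
   Per-stack, not per-slice, so relative uptake across slices survives.
4. `to_uptake()`: `100 * v / 255`, the 0-100 relative-uptake scale on
   which all quantification operates.

## The translation model

`train_translation()` trains unpaired generators G_SP (SPECT to PET) and
G_PS with one least-squares patch discriminator per domain, minimizing
`adv_S + adv_P + cycle_weight * cyc + identity_weight * idl`, where `cyc`
pools the mean absolute reconstruction error of both round trips and
`idl` is the identity term `|G_SP(P) - P| + |G_PS(S) - S|`.
`cycle_weight = 10` follows the convention of the cycle-consistent
architecture family (the source prints no loss weights); the identity
term (weight `0.5 * cycle_weight`, that family's customary optional
anchor) is on by default because cycle consistency alone leaves a gauge
freedom — one generator can uniformly dim every image and the other
brighten it back at zero cycle cost — and at desk scale the adversarial
game otherwise drifts along that mode.

The generators are narrow 3-level U-Nets whose zero-initialized head
outputs a *multiplicative* gain field, `y = x * (1 + f(x))`: the natural
parameterization of an attenuation correction (a dark background cannot
be brightened, an untrained generator is exactly the identity, and the
learning signal concentrates on the myocardium). No deep-learning
framework exists for R in the supported environment, so the layers (3x3
same convolutions lowered to BLAS matrix products by a C++ im2col, mean
pooling, nearest-neighbor upsampling, leaky ReLU) and their backward
passes are implemented in the package and verified against finite
differences in the test suite.

Getting an adversarial game this small to converge reproducibly required
four measures, each diagnosed by tracking discriminator separation
`D(real) - D(fake)` per epoch rather than by tuning on any acceptance
metric. (1) The patch discriminators first mean-pool and per-image
standardize their input: the two domains differ in pixel-level noise
texture and, after per-stack maximum normalization, in global amplitude
(sharper PET noise inflates the PET maximum); an unnormalized classifier
latches onto those nuisances instead of the attenuation structure and
drags the generators into global brightness oscillations. Three further
downsampling levels give a receptive field of roughly a myocardial arc —
with less reach the classifier collapses to a constant. (2) The
discriminators use Adam at five times the generator learning rate: their
LSGAN gradients are orders of magnitude too small for plain SGD at the
published rate, and an untrained discriminator pins the generators at
identity because the cycle term dominates. (3) Training opens with a
discriminator-only warmup (default 400 steps): the generators start as
exact identities, so the warmup teaches the discriminators the true
domain difference before the game begins. (4) A history buffer of past
fakes and global-norm gradient clipping damp the remaining oscillation.

Two profiles are named in `train_config()`. The `"paper"` profile keeps
the published recipe: 256 x 256 inputs, 50 epochs, batch 8, learning
rate 0.002, SGD with momentum 0.9 — the published text names only a
"momentum optimizer", so the classical reading is the generator default
(Adam is exposed as a config option). The `"desk"` profile (64 x 64
inputs, width-6 U-Net, 16 epochs over the slice pool, a few hundred
adversarial iterations) keeps the same generator optimizer and learning
rate. Stress and rest models are trained separately (mirroring the
separate stress/rest pair counts); training is deterministic for a fixed
seed.

## Segment quantification

`segment_table()` implements the polar-profile statistic: the stack is
split into seven near-equal longitudinal divisions (larger divisions
toward the base; divisions 1-2/3-4/5-6/7 forming basal/mid/apical/apex
rings), and on every slice 360 per-degree radial profiles are taken from
the LV center (intensity centroid of the middle slice by default,
overridable) to the inscribed radius, each profile scored by its maximum
under half-pixel bilinear sampling. A segment's representative value is
the mean of its per-angle maxima over all its slices — 60 profiles per
slice for a basal/mid segment, 90 for an apical one, 360 for the apex.
Profiles are taken over the full ray (the background is dark, so the
myocardium dominates); an endocardial/epicardial band restriction was
considered and rejected as it requires surface segmentation that the
statistic is designed to avoid. The implementation is held to within
1e-9 of an explicit-loop oracle in the tests.

## Metrics, scoring, ROC

* `nrmse()` divides the RMSE by the reference dynamic range; the source
  does not define its normalizer, and range normalization is the
  interpretation consistent with the magnitude of its reported values.
  `psnr()` uses peak 100 (the uptake scale; 255 available for raw 8-bit).
  `ssim()` uses the literature defaults (11 x 11 Gaussian window, sigma
  1.5, K1 = 0.01, K2 = 0.03, L = 100), computed per slice on the fully
  windowed region.
* `grade_uptake()` applies the five printed bands (75/65/50/40) closed on
  their lower bound, on uptake relative to the per-study segment maximum.
  `score_case()` floors negative stress-rest differences at zero (the
  reversibility convention; configurable). The deterministic band rule
  replaces the three-reader consensus scoring, which the source states
  used exactly these bands as its reference.
* `roc_defect_detection()` uses the rank (Mann-Whitney) AUC with ties
  mid-ranked and reports the Youden-optimal operating point (ties broken
  toward the more specific threshold). Defect presence in a territory
  means a summed stress, rest, or difference score of at least 1 there;
  the territory map is the standard LAD/RCA/LCX assignment and is
  overridable.
* `paired_segment_comparison()` mirrors the segment-wise testing design:
  per segment, a Shapiro-Wilk screen at alpha 0.05 chooses between the
  paired t-test and the Wilcoxon signed-rank test, two-sided at alpha
  0.05, uncorrected (as in the source's per-segment asterisks).

## Numerical choices and degenerate inputs

All-zero stacks quantize to all-zero with unit scale; a zero-dynamic-range
reference makes NRMSE an error rather than NaN; identical stacks report
PSNR = Inf as the MSE = 0 sentinel; images smaller than the SSIM window
fall back to one uniform window; single-class truth vectors make ROC an
error (the pipeline records the degenerate cohort instead of a number);
stacks with fewer than 7 slices are partitioned with a warning (every ring
keeps at least one slice), fewer than 4 are rejected.

## What the acceptance suite establishes

The printed worked-example rules (60 profiles, 7 divisions, 1.5
magnification, 255 -> 100, 17 segments, moderate band ending at 64) are
checked exactly. The parameter-recovery experiment — cohorts with
inferior attenuation (`min_factor` 0.8), no true defects, desk-scale
training — requires the mean absolute error of inferior segments #4/#10/#15
against PET to drop by at least half after translation in at least 4 of 5
seeds. The null control re-runs the segment comparison with attenuation
disabled and requires that no segment is significant in 4 or more of 5
seeded cohorts: a replication criterion, because with 17 uncorrected
tests at alpha 0.05 even a perfect pipeline would flag ~1 segment per
cohort by chance, while a genuine geometry or interpolation bias would
replicate across seeds. The clinical figures of the motivating study
(NRMSE/PSNR/SSIM means, territory AUCs) are not reproduction targets:
they require the original, undeposited patient data.

## Known limitations

The phantom's regular geometry makes the translation task easier than
clinical attenuation correction; defect disappearance through
overcorrection — a real failure mode of PET-supervised translation — is
observable in the pipeline (feed a cohort with true inferior defects) but
no criterion is attached to it; the desk-scale discriminators are small
and the adversarial equilibrium is correspondingly coarse; and the CLI
reads whole stacks into memory, which is fine at 128 x 128 but not
engineered for larger matrices.
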