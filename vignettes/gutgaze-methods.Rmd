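---
title: "Gaze-based bowel annotation: model, phantoms, and agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-based bowel annotation: model, phantoms, and agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutgaze)
```

## The problem

Bowel obstruction is diagnosed on CT by following the gastrointestinal tract
and judging its caliber: roughly 3 cm is the dilation threshold for small
bowel and 6 cm for large bowel. Training automated methods to do this
requires voxel-level annotations, and manual tracing of the whole gut in a
512 x 512 x ~128 scan is prohibitively slow. Gaze-based ("visual")
annotation replaces tracing with looking: an eye tracker records where a
radiologist casts their gaze while they scroll along the bowel, a knob
records their running estimate of the bowel diameter, and a geometric model
turns these sparse centerline samples into dense volumetric labels and a
per-voxel diameter map.

`gutgaze` implements that pipeline end to end: the annotation data model,
the centerline-to-volume reconstruction, a synthetic CT phantom generator
with exact ground truth, normalization and geometry-preserving augmentation,
a small dual-output U-net that predicts segmentation and diameter jointly,
and the agreement statistics (Dice, two-way-agreement ICC, Bland-Altman
limits of agreement) used to quantify repeatability and cross-method
agreement.

## The annotation model

A *gaze point* is a 3-D world-coordinate position (mm) with an
annotator-set diameter. The eye tracker samples at 60 Hz and positions are
averaged over 0.75 s intervals, so one gaze point summarizes
`round(60 * 0.75) = 45` raw samples. A *visual segment* is an ordered run
of gaze points tracing one stretch of bowel, labeled with one of 13 parts
(esophagus through anus). Segments are short in practice — the bowel's
course is rarely apparent for long — so a scan accumulates dozens of them.

Two accounting rules matter downstream: the recording time of an annotation
is `0.75 s x n_gaze_points` (the dwell is a parameter of
`annotation_summary()`; 0.75 s is the default), and a segment's length is
the sum of distances between sequential gaze points. These identities, run
over the package's own accounting functions, reproduce the per-segment and
per-scan effort figures that motivate the approach (about 10.7 s and about
97.5 mm per segment; about 10.6 min per scan).

For analysis the 13 parts collapse to foregut (esophagus-duodenum), midgut
(jejunum-ileum) and hindgut (cecum-anus). The grouping follows obstruction
thresholds rather than embryology: the duodenum sits with the foregut
because the duodenal bulb can exceed the small-bowel threshold at baseline,
and the proximal colon sits with the hindgut because its threshold matches
the distal colon's.

## Reconstruction: nearest segment within half a diameter

For every voxel center (world mm — all geometry is computed in physical
coordinates so anisotropic voxels, e.g. 0.75 x 0.75 x 3.72 mm, are handled
correctly), the closest segment is found. If the distance is within half
the segment's local diameter, the voxel takes that segment's label,
otherwise background. The diameter map assigns the local diameter of the
closest segment the same way.

Design choices that the contract leaves open, and how this package resolves
them:

* **Distance primitive.** Distance is measured to the *polyline* through
  the gaze points (clamped to endpoints), with the diameter linearly
  interpolated at the nearest parameter. Gaze points are about 7 mm apart
  on average, so point-to-point distance alone would leave scalloped gaps
  between them. A `"points"` mode is retained for ablation.
* **Masking.** By default the diameter map is zero outside the
  reconstructed bowel (`masked_diameter = TRUE`). A dense variant that
  assigns every voxel the nearest segment's diameter is available; the
  masked default matches the training regime, where the loss up-weights
  exactly the non-zero voxels.
* **Ties.** Equidistant segments resolve to the lowest segment index —
  recording order — which makes the output deterministic.
* **Voxel membership.** Decided at the voxel center, with
  `world = origin + index * spacing` (0-based indices). This convention is
  pinned down so that `reconstruct()` and the naive per-voxel reference
  implementation `brute_force_reconstruct()` agree *bit-exactly*; the test
  suite enforces that equivalence on randomized annotations and grids.

## The phantom generator

No public CT cohort with gaze annotations exists, so every downstream stage
is exercised on synthetic tubular phantoms with exact ground truth.
`generate_phantom()` emulates the contrast regime of an unprepared abdomen:
fat background (about -100 HU) with soft-tissue regions (about 40 HU),
bowel wall at soft-tissue attenuation (3 mm by default), lumens of gas
(about -1000 HU) or fluid (about 10 HU), and additive Gaussian noise
(15 HU). Tubes follow smoothed random-walk centerlines with slowly varying
diameter profiles; truth labels and diameters come from the exact
centerlines via the same nearest-segment contract as `reconstruct()`.

Deliberate simplifications:

* **Tubes never overlap** (rejection sampling). Real bowel loops touch;
  non-overlap keeps the ground truth unambiguous, which is the property the
  phantoms exist to provide.
* **Default diameters span 10-60 mm**, normal to clearly dilated bowel, as
  appropriate for a full abdominal field of view (about 380 mm). Tests that
  run on small grids (128 mm and below) use 8-30 mm calibers, because a
  60 mm tube plus wall clearance cannot be placed in such a volume at all —
  the generator raises an error rather than silently shrinking anything.
* **No peristalsis, no anatomic topology, no contrast phases.**

`simulate_gaze_recording()` emulates the eye tracker: raw samples march
along the true centerline (default 0.155 mm per sample, chosen so gaze
points land about 7 mm apart, matching the observed spacing of roughly
97.5 mm per 14.3 points), each perturbed by isotropic Gaussian jitter, and
blocks of 45 samples are averaged into gaze points. The recorded diameter
is the true local diameter plus Gaussian error, quantized to the 1 mm knob
step and floored at one step. Two details worth knowing:

* A trailing partial block becomes a final gaze point if it holds at least
  half a block of samples, and is dropped otherwise — short segments are
  never empty.
* The jitter and diameter-error draws are standard normals scaled by their
  standard deviations, so one seed produces the *same underlying noise
  field* at every noise level. Comparisons across jitter settings are
  paired, which is what makes the mean repeatability Dice decrease strictly
  across jitter 0, 1, 2, 4 mm with only ten seeds.
* With zero noise, block averaging still commits a tiny chord error on
  curved centerlines (the mean of samples along an arc lies slightly inside
  the curve); on the generator's smooth tubes this stays well under half a
  millimetre.

The real eye tracker's error is heteroskedastic across the monitor and
calibration-dependent; the isotropic stationary model here is a stand-in,
so passing repeatability tests on phantoms bounds geometry-driven
variation, not operator- or hardware-driven variation.

`simulate_calipers()` places short/long-axis caliper pairs at random
centerline sites where the tube runs within 30 degrees of the z-axis (en
face to the axial plane), mirroring how manual reference measurements are
taken.

## Normalization and augmentation

* CT intensities map to [-1, 1] with window 400 HU / level 40 HU,
  `clip(2 (v - level) / window, -1, 1)`. Clipping at the window edges is
  the standard window/level semantics.
* Diameters convert from mm to voxel units by dividing by the *in-plane*
  voxel size (axial measurements; slice thickness is not a natural diameter
  unit). Voxel units decouple the regression target from field-of-view and
  patient-size variation; multiplying by the known voxel size recovers mm.
* Resizing to the model input (256 x 256 slices for 2d, 128 x 128 x 64 for
  3d) interpolates the image linearly and everything categorical or
  count-valued (labels, diameters, weights) by nearest neighbor, so label
  codes are preserved and diameter *values* are untouched. The 3d path
  zero-pads the slice axis to the next multiple of the target so z is
  decimated by an integer factor, never interpolated. Padding is applied in
  normalized space with image fill -1 (air maps to -1 under the window),
  labels and diameters 0, weights 1.
* Augmentation composes one affine in physical mm space — magnification in
  [0.7, 1.3], rotation up to +/-30 degrees per axis (order Rz Ry Rx, about
  the volume center), in-plane translation up to +/-30 mm — and resamples
  onto the original grid. Working in mm preserves shape despite voxel
  anisotropy: the tests verify a rotated sphere stays a sphere
  (Dice >= 0.95 against the analytic mask on a 1 x 1 x 3 mm grid). Diameter
  values are multiplied by the magnification factor so voxel-unit diameters
  stay consistent with the magnified geometry.
* Sample weights are `foreground_weight` (default 10; bowel occupies a few
  percent of an abdominal volume) on non-background voxels and 1 elsewhere.

## The network and its loss

`build_unet()` constructs a U-net from `2 * n_levels` blocks; each block is
conv-ReLU-conv-ReLU-batchnorm-dropout, with 2x maxpool on the way down, 2x
nearest-neighbor upsampling and a skip concatenation on the way up, and
channel count doubling per level. Two heads leave the final full-resolution
level: a 4-class softmax (background + 3 gut parts) and a diameter
regression through a softplus, which guarantees non-negative diameters with
smooth gradients. Reference-scale configurations are 256 x 256 x 8 channels
with 7 levels (14 blocks, 2 x 2 midpoint) for 2d and 128 x 128 x 64 x 16
channels with 5 levels (10 blocks) for 3d; at 5 levels the 3d midpoint is
4 x 4 x 2, and the block count is the anchoring constraint. Exact per-level
filter schedules are not uniquely determined by those constraints; this
package doubles channels per level and reports the resulting parameter
count, which grows roughly fourfold per added level.

The per-voxel loss is

$$L = L_{CE} + L_{BCE} + \lambda\, L_{SE},$$

with \(L_{CE} = -\sum_{k=0}^{3} t_k \log p_k\) the 4-class cross-entropy
(background is a class), \(L_{BCE} = -t_0 \log p_0 - (1 - t_0)\log(1 -
p_0)\) the binary cross-entropy of the background-vs-gut dichotomy (it
favors separating bowel from background even when the part is ambiguous),
and \(L_{SE} = (d_t - d_p)^2\) the squared diameter error in voxel units.
Each voxel's loss is multiplied by its sample weight and averaged.
\(\lambda\) defaults to 0.01, which puts typical squared diameter errors
(tens to hundreds of square voxels) on the order of the cross-entropy
terms; `lambda = "auto"` estimates the balance from the first batch
instead. The implementation's analytic gradients are verified against
numerical differentiation and an independent scalar-loop loss in the test
suite.

Training uses Adam (default learning rate 1e-3) for a fixed number of
epochs (default 100), with 10% of samples held out by a seeded split and
the best-validation-loss weights returned. The whole engine — im2col
convolutions, batchnorm, pooling, backprop — is plain single-threaded R
matrix arithmetic, which makes runs bit-reproducible from the seed. It is
deliberately desk-scale: `desk_unet_config()` (64 x 64 inputs, 3 levels, 4
base channels, about 15k parameters) trains in about a minute and is what
the tests exercise. Full-batch training takes one optimizer step per epoch,
far too few for the diameter head to reach outputs of tens of voxels within
100 epochs, so the overfitting checks use `batch_size = 2` and a learning
rate of 0.02; both are explicit `train_unet()` parameters.

## Agreement statistics

* **Dice**: `2 |A n B| / (|A| + |B|)`, per part and for the whole
  foreground. When a part is absent from *both* sources on a scan the score
  is undefined and that scan is excluded for that part (its `n` drops);
  absent from exactly one counts as 0. The "empty in both" exclusion is the
  default (`compare_sources(exclusion = "both")`) with "either" available.
* **ICC(A,1)**, two-way random-effects, absolute agreement, single rater:
  \((MS_R - MS_E) / (MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E))\), with
  the 95% CI from the F-based approximation (McGraw & Wong). Absolute
  agreement penalizes systematic offsets between raters, the relevant
  notion for repeated diameter measurements. The implementation computes
  the mean squares in closed form and is tested to 1e-10 against an
  independently coded `stats::aov` route. A zero-total-variance input is
  degenerate: ICC is defined as 1 and flagged.
* **Bland-Altman**: bias = mean difference, 95% limits of agreement =
  bias +/- 1.96 x sample SD of differences.

`compare_sources()` runs the whole comparison between two per-scan sources
(repetition vs repetition, annotation vs prediction), sampling diameters at
shared sites with `sample_diameter_at()` — on a masked map a zero at the
nearest voxel falls back to the nearest non-zero voxel within a search
radius (default 5 mm), which is how caliper sites just off the
reconstructed lumen are matched. Manual caliper pairs enter as the mean of
short and long axis by default (`pair_calipers_with_map()`), configurable
to short- or long-only; when both annotation repetitions are compared
against one reference, the pairs are pooled.

One measurement convention: the phantom round-trip checks report the
diameter MAE over voxels reconstructed as bowel in *both* the truth and the
reconstruction. Mask disagreement is Dice's job; mixing boundary-mask
mismatches (|0 - 25| mm) into a diameter error statistic would measure
overlap twice and caliber accuracy not at all.

## Problem sizes used in tests

The suite runs entirely on synthetic data built at test time: oracle
equivalence on grids up to 24^3, the noiseless round-trip on a 1 mm 128^3
phantom (Dice >= 0.90, in-bowel MAE <= 1 voxel), repeatability
monotonicity on 80^3 phantoms over ten seeds, and the learning check on
eight 64 x 64 slices for 100 epochs at three seeds (passing if at least two
reach training Dice >= 0.8 and diameter MAE <= 2 voxels). These sizes keep
the full suite under ten minutes on one CPU while still exercising every
contract at meaningful scale.

## Known limitations

* Phantom tubes are topologically trivial; performance on real, touching,
  collapsed or fluid-filled bowel is out of reach of these tests.
* The gaze noise model is isotropic and stationary; real calibration error
  is neither.
* The training engine is desk-scale by design: it demonstrates that the
  architecture and loss learn the task, not that they reach
  clinical-cohort accuracy. Reference-scale configurations build and
  predict, but training them in R at full size is impractical.
* Whether the recorded effort accounting should include discarded or redone
  segments is unknowable from summaries alone; `annotation_summary()`
  counts retained points only.
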