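---
title: "echoqc: models, phantom design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{echoqc: models, phantom design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`echoqc` scores apical four-chamber (A4C) echocardiography videos against a
five-point clinical quality-control protocol and explains every lost point.
This vignette documents the science and engineering choices behind the
package: the models and their assumptions, the tunable parameters, what the
synthetic phantom does and does not emulate, and the numerical conventions.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The protocol and its gate

A video is scored per cardiac cycle, starting from 0:

* **Complete cardiac cycle** — a consecutive ED–ES–ED or ES–ED–ES keyframe
  triple. This is a *gate*: without it the total is 0 and no other
  criterion is evaluated, because a clip without a full cycle has no
  diagnostic value regardless of its appearance.
* **Gain** (+1) — the ES target frame is classified low / medium / high;
  only medium scores.
* **Depth** (+1) — `D = h2 / h1`, the vertical extent of the union of all
  detected structure boxes over the image height, must lie in the open
  interval (0.5, 0.75).
* **Cardiac-axis angle** (+1) — `C`, the angle of the left-ventricle
  detection box's major axis against the image x-axis, must lie in
  (75°, 95°); 90° is a vertical axis.
* **Anatomical structures** (+2) — LV, RV, LA, RA and the interventricular
  septum must each be detected at confidence ≥ 0.25 in *both* the ED and
  the ES target frame. The mitral and tricuspid valves are annotated and
  detected but never affect the score (they are invisible in a meaningful
  fraction of healthy subjects).

All criteria are evaluated on the ES frame except the structure check,
which uses both target frames. A video's score aggregates its per-cycle
cards with `max` by default: an operator looks for at least one standard
cycle. `min` and `first` are available (`scoring$aggregate`); the protocol
itself does not prescribe multi-cycle aggregation, so this is a documented
package choice.

The depth and axis thresholds above are the operational, statistically
calibrated ranges (normal means D ≈ 0.618, C ≈ 84.5°). The protocol's
verbal ranges — silhouette covering 2/3 to 4/5 of the sector, axis within
±20° of vertical — are available as `threshold_preset("protocol")`. The
two formulations are *not* equivalent; the package preserves both and
defaults to the operational one, correcting neither.

Open-interval semantics are deliberate: a measurement exactly at a
threshold fails. This is deterministic and conservative; with continuous
measurements the boundary case has measure zero anyway.

## 2. Phase analysis: the volume curve

The left-ventricular volume curve (LVVC) is the supervision signal for
phase analysis. Between a consecutive ES at `f_es` and ED at `f_ed`:

$$y(x) = \sin\!\Big(\tfrac{3\pi}{2} - \pi\,\tfrac{f_{es}-x}{f_{ed}-f_{es}}\Big)
\quad\text{(diastole)},\qquad
y(x) = \sin\!\Big(\tfrac{3\pi}{2} + \pi\,\tfrac{x-f_{es}}{f_{es}-f_{ed}}\Big)
\quad\text{(systole)}.$$

ED frames evaluate to exactly +1 and ES frames to −1; the curve is
continuous at the junctions. Frames outside the labeled span have no
defined value: `lvvc_ground_truth()` returns them as `NA` with a `FALSE`
supervision mask, and the training loss is masked accordingly. The phantom
generator instead requests `extend = TRUE` (periodic continuation mirroring
the adjacent segment), so phantom curves are fully supervised.

**Keyframe extraction** inverts a predicted curve: local maxima become ED,
local minima ES. The defaults are a centered moving average of
`smooth_window = 3` frames, topographic prominence ≥ `min_prominence = 0.3`
(the curve's amplitude is 2, so this cannot merge genuine phases), and
`min_separation = 5` frames between keyframes of the same phase (a typical
cycle spans ~46 frames, so same-phase extrema are ≥ ~40 frames apart).
Plateau extrema take the left-most frame (determinism). Two edge rules
matter:

* extrema at the edges of the *supervised span* (abutting `NA` frames) are
  always admitted — ground-truth curves place exact keyframes there;
* extrema at the raw start/end of the curve are admitted only when they
  reach the amplitude established by the curve's other extrema (within
  20 % of the range). A cycle truncated mid-segment produces a rising or
  falling tail whose endpoint is a spurious local extremum; admitting it
  would fabricate keyframes and, worse, fabricate complete cycles on
  incomplete videos. A genuine keyframe at the video edge sits at full
  amplitude and passes the gate (at worst shifted by a frame or two).

**Cycle completeness** enumerates all stride-1 alternating triples, so
consecutive cycles share keyframes; the protocol never says whether cycles
may overlap, and reporting all of them is the informative choice. QC
targets of a cycle: the ES keyframe (mid of ED–ES–ED, start of ES–ED–ES)
and the ED keyframe nearest the cycle start. Which ED of an ED–ES–ED
cycle is "the" target is not specified anywhere; the start-ED is a
documented tie-break, and since ground-truth cycles are periodic the choice
does not affect any score.

## 3. Oriented boxes, CSL, and quantification

Boxes use the long-side convention: `w ≥ h`, `theta` ∈ [0, 180) is the
angle of the long side against the +x axis, measured in the y-down image
frame. This makes the LV box angle directly the cardiac-axis estimate.
Rotated IoU is exact (Sutherland–Hodgman convex clipping + shoelace area);
the test suite cross-checks it against a 100 000-point Monte-Carlo
point-in-polygon oracle on 200 random pairs (criterion: |Δ| < 0.01).

Angles are learned as a circular classification problem (circular smooth
labels): 180 one-degree bins by default, target 1 at the angle's bin with a
Gaussian fall-off `exp(-d²/(2r²))` up to radius `r = 6` bins, wrapping
across 0/180. `csl_decode()` is the plain argmax (ties to the smallest
bin). The trainable detector head uses 36 five-degree bins
(`detect$n_angle_bins`, radius 2) for desk-scale efficiency and refines the
argmax with a softmax-weighted circular mean over ±2 bins, so its angular
resolution is not limited to the bin width.

`depth_ratio()` measures `h2` as the vertical extent of the union of all
detection corner polygons (`h2_mode = "union"`; the whole-heart silhouette
is what the depth setting controls). `"max_single"` (largest single box)
is available. `h1` is the full image height; for sector-cropped inputs
override it at the call site. `caa_angle()` uses the highest-confidence LV
detection. After NMS, only the highest-confidence detection per label
feeds quantification (`top_per_label()`): a duplicate far-away false
positive would otherwise corrupt the union extent. Missing inputs (no
detections; no LV) yield "not computable" results that score 0 with an
explanatory reason, distinct from an out-of-range measurement.

## 4. The trainable stack

The published system this package re-implements couples a YOLOv5 backbone
with a CSL rotation head, a Bi-LSTM phase regressor and a gain classifier.
Reproducing that exact architecture is neither possible nor meaningful at
desk scale; what `echoqc` fixes are the *contracts* — shared backbone,
staged training, loss structure, head outputs — with a small configurable
convolutional pyramid, entirely in base R (im2col convolutions on BLAS,
hand-written backprop, Adam):

* **Backbone** — three stride-2 stages (channels 8/16/32) and a dilated
  stride-1 tail (dilations 1, 2, 2), giving a stride-8 grid (16×16 at the
  128×128 phantom resolution) with a ~95-pixel receptive field. The wide
  field is what disambiguates the four chambers (the heart spans ~0.6 of
  the image); the fine stride is what localizes the thin valve bars.
* **Detection head** — a 1×1 convolution emitting, per cell and per class:
  a presence logit, in-cell center offsets (sigmoid), log width/height,
  and CSL angle logits. Box and angle predictors are *per class*: an A4C
  frame carries at most one instance of each structure, so class-specific
  regressors cannot collide when two structure centers share a cell. The
  loss is weighted binary cross-entropy on the class maps (positive weight
  50; classes entirely absent from a frame — dropped structures — have all
  their cells up-weighted ×10, since with heavily up-weighted positives a
  plain background weight would make hallucinating an absent structure
  almost free), squared error on offsets and log sizes at positive cells,
  and soft cross-entropy against the CSL target. Offset residuals are
  weighted by
  `stride/extent` (clamped to [0.5, 3]) per axis — an IoU-aware weighting:
  one pixel of center error is negligible for a ventricle but fatal for a
  4-pixel-high valve bar at an IoU 0.5 match threshold.
* **Phase head** — global-average-pooled backbone features per frame,
  standardized per video (per channel over time; this removes inter-video
  appearance offsets and is the package's resolution of the unspecified
  pooling between backbone and recurrent head), feeding a 2-layer
  bidirectional LSTM (hidden 24) with a linear read-out, trained with
  masked MSE against the LVVC on fixed 60-frame windows guaranteed to
  contain the labeled triple. Shorter videos are edge-padded with the
  padding masked out. Predictions are clipped to [−1, 1].
* **Gain head** — softmax regression on statistics-pooled deep features
  (per-channel mean *and* spatial standard deviation of the last feature
  map), with a small L2 penalty (1e-4). Mean-only pooling is measurably
  gain-starved here: detection training pushes the backbone towards
  gain-invariant responses, and the second moments retain much more of the
  intensity regime. This stays within the "deep features, pooled, fully
  connected" contract.
* **Staged training** — the detector trains first (it needs the most
  detailed features); the backbone is then frozen — phase and gain updates
  never touch it, verified bitwise in the tests — and the two heads train
  on the shared features. Optimizer is Adam (lr 1e-3 default, 2e-3 in the
  acceptance recipe) with a ×0.3 step decay over the final 30 % of epochs;
  one master seed drives weight init, data order and phantom generation,
  making loss traces exactly reproducible.

`run_qc()` executes the same pipeline in learned and oracle mode: curve →
keyframes → cycle gate → targets → detections on ED/ES → structure check,
depth, CAA on ES → gain on ES → score cards → report. Oracle mode swaps in
ground-truth curve, boxes (confidence 1) and gain class but goes through
the identical post-processing path. Throughput (frames/s) is recorded on
the report attribute but never asserted: it is hardware, not science.

## 5. The phantom: a stated world

The phantom renders what the pipeline *consumes*, not what ultrasound
looks like. A fan-shaped sector (apex top-center, 38° half-angle) holds
seven structures: four chambers as dark filled ellipses, the septum as a
bright bar, the valves as thin low-contrast bars (so that dropout tests of
the "valves optional" rule are meaningful). The ensemble is rotated to the
requested axis angle and scaled so that the ground-truth depth ratio on the
ES frame equals the requested `depth` exactly. LV and RV semi-axes scale
as `sqrt(1 + a·y(t))` (a = 0.35 / 0.25), so the LV *area* is linear in the
volume curve; the rendered LV mask area correlates with the curve at
r > 0.99 (tested). Gain regimes: low = ×0.4, high = ×1.8 with clipping and
extra Gaussian noise (σ = 0.05), medium = identity — excess gain saturates
and blurs, deficient gain crushes contrast. Multiplicative Rayleigh-like
speckle (mean 1, strength `speckle_sigma = 0.08`) is first-order ultrasound
texture without physics.

Defaults are the stated world: 60-frame videos (the training segment
length), cycle length 46 frames (the average clinical A4C cycle at
conventional frame rates), depth 0.62 and axis 85° (the clinical normal
means), medium gain, no dropout. `generate_dataset()` stratifies over
target scores 5/4/3/2/1/0 — rotating the failed criterion for 4, combining
failures for lower totals, dropping an essential structure for 1, and
truncating below one cycle for 0 — with in-band values drawn from
(0.55, 0.72) and (78°, 92°) and out-of-band values from the flanking
intervals. Every video's ground truth carries keyframes, the full-span
curve, per-frame boxes, gain class, depth, axis and an expected score card
recomputable through the scoring module itself (self-consistency is a
test).

What the phantom does *not* emulate — and therefore what a green test does
not establish: real speckle statistics and attenuation, anatomical shape
variability and pathology, probe motion, arrhythmia (cycles are strictly
periodic), ECG, and annotation noise (phantom labels are exact). Learned
components proven on phantoms demonstrate that the *pipeline and training
machinery* work end-to-end, not clinical performance.

## 6. Numerical choices and degenerate inputs

* 0-based frame indices in every schema and report; R's 1-based indexing
  is internal only.
* Constant phase curves yield an empty keyframe list (not an error); a
  video without a complete cycle yields a valid report with total 0 and a
  single gating card carrying the reason.
* `theta` is normalized modulo 180 everywhere; decoded boxes with
  `h > w` are swapped and rotated by 90°.
* NMS is greedy by descending confidence, stable on ties, class-wise.
* Frame-error matching is greedy nearest-same-phase, one-to-one, ties to
  the earlier prediction; unmatched ground truths are reported as misses,
  not folded into the mean. The source protocol never defines this rule.
* AP uses all-point interpolation (the modern convention; the test suite
  checks it against an exhaustive threshold-sweep oracle); mP/mR are read
  at the fixed confidence 0.25 — whether the published numbers use a fixed
  or best-F1 operating point is unstated.
* Cohen's kappa is unweighted; two constant-but-different raters give
  kappa 0 with a warning (the 0/0 convention).
* PGM (P2/P5) is the native frame format; PNG is read when the `png`
  package is installed. This is an environment-driven narrowing of the
  frame-stack contract, documented here rather than hidden.
* The achievable score totals are exactly {0, 1, 2, 3, 4, 5}, verified by
  exhaustive enumeration over the criterion states and the gate.

## 7. Known limitations

Pure-R training is desk-scale by design: minutes, not hours, and phantom
resolution 128×128 rather than the 512×512 that clinical detection
favours. The detector is a single-scale dense head, not a multi-scale
anchor design; it is adequate for the phantom's 7 structures but is a
contract stand-in, not a clinical detector. The gain head is linear on
pooled statistics; clinical gain assessment would want calibration across
vendors. Scores are discrete by protocol — the package deliberately does
not emit continuous quality values.
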