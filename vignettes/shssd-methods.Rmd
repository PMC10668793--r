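---
title: "Counting sheep by detection, tracking and line crossing: the shssd methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting sheep by detection, tracking and line crossing: the shssd methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shssd)
```

## The problem

Flock inventories on sheep farms are still largely counted by eye at a
corridor gate. `shssd` implements an automated alternative built from three
stages: a lightweight single-shot head detector (SH-SSD), a
tracking-by-detection stage that stamps a persistent identity on each head,
and a virtual counting line that tallies animals as their head centers cross
it. The head — rather than the body — is the detection target because heads
stay visible from an overhead camera even when densely packed bodies
occlude one another.

Everything in the package runs on plain CPU R: the network layers
(convolution via im2col/GEMM in C++, batch normalization, ReLU6, attention
gates) are implemented in the package itself with exact hand-derived
backward passes, verified against finite differences in the test suite.

## The detector

SH-SSD is an SSD-lineage one-stage detector with three parts.

**Backbone.** A MobileNetV3-flavoured stem plus six inverted-bottleneck
stages ("TAneck" modules: 1×1 expansion, depthwise k×k, optional attention,
1×1 projection, residual when shapes agree), interleaved with plain
convolution–batchnorm–ReLU6 (CBR) blocks. Where MobileNetV3 would apply
squeeze–excite attention, the TAneck uses a *triple attention* (TA) block:
three branches pool (max and mean) along the channel, height and width axes
respectively, squeeze the two pooled maps through a 7×7 convolution,
batch-norm and sigmoid into a gate, multiply the gate back onto the input,
and average the three gated tensors. A TA block costs exactly
`3 × (2·1·7·7 + 2) = 300` parameters regardless of the channel count — the
7×7 convolutions carry no bias because a batch-norm immediately follows —
which is why swapping SE for TA leaves the backbone parameter count nearly
unchanged (2.98 M → 2.97 M) while adding spatial attention.

Three taps export features at strides 8, 16 and 32. The per-layer
configuration lives in one declarative table, `backbone_config()`. The
published architecture fixes the layer *pattern* and the parameter totals
(2.97 M backbone, 6.44 M complete detector) but not every width; the widths
in the table were chosen once so that the deterministic parameter count
reproduces those totals exactly, and `audit_params()` recomputes the audit
at any time:

```{r audit, eval = FALSE}
audit_params("full")
#>   attention backbone    neck  heads   total backbone_M total_M
#> 1        ta  2968088 3316732 158157 6442977       2.97    6.44
#> 2        se  2979566 3316732 158157 6454455       2.98    6.45
#> 3      none  2967488 3316732 158157 6442377       2.97    6.44
```

**Neck.** Instead of FPN-style cross-scale fusion, each backbone tap gets
its own independent branch: two depthwise CBR blocks, spatial pyramid
pooling (concatenation with 5/9/13 stride-1 max-pooled copies, quadrupling
channels) on the stride-8 and stride-16 branches, two CBR blocks reducing to
a common width of 96 channels, then a stack of TAneck modules (five on the
first branch, four on the others — ten, nine and eight modules per branch in
total). No tensor from one branch ever feeds another; the test suite
verifies branch independence by perturbation.

**Head.** One decoupled head (DCHead) per branch: a shared 1×1 CBR stem,
then separate classification and regression stacks (two sets of
DW-CBR + CBR each, following the published head description) ending in
biased 1×1 prediction convolutions. Decoupling avoids the spatial
misalignment between classification and localization signals that shared
heads suffer from. Three square anchors per cell per level (scales
`{32, 64, 128} × 2^(0,1,2)/3`, ratio 1:1 — head boxes are near-square)
are decoded with the standard SSD offset parameterization; greedy
class-wise NMS at IoU 0.5 prunes duplicates. Score thresholds default to
0.05 for evaluation and 0.4 for tracking input. The head predicts no
separate objectness channel — the drawn head shows only classification and
regression branches — so scores are per-class sigmoids.

## Training: dynamic sample matching

The training-time label assignment adapts to the current predictions
instead of a fixed anchor-IoU rule. The method is named but not specified
in print, so the package implements a documented SimOTA-style
reconstruction (the closest published "dynamic matching" in the
decoupled-head lineage), with every constant exposed:

* candidates: anchors whose center lies inside a ground-truth box or
  within 2.5 cells of its center;
* cost: binary cross-entropy of the predicted score against the target,
  plus `λ = 3` times `−log IoU` of the decoded predicted box;
* budget: each ground truth takes its `k` lowest-cost candidates with
  `k = clamp(⌊Σ top-10 candidate IoUs⌋, 1, 10)`;
* conflicts: an anchor claimed twice goes to the lower-cost ground truth,
  and any ground truth left empty reclaims its single cheapest candidate.

The loss is the SSD default (the source never states its loss): binary
cross-entropy with 3:1 hard-negative mining plus smooth-L1 on the encoded
offsets, both normalized by the positive count. The classification bias is
initialized to the background prior (π = 0.01), the usual stabilizer for
one-stage detectors where negatives outnumber positives by three orders of
magnitude. Whether the original method used an ignore band or per-level
candidate restriction is unknowable from the text; none is used here.

Optimization is Adam at the published schedule (learning rate 5e-4, batch
32, step decay every 100 epochs, 300 epochs) by default. The package's own
CPU-scale overfitting experiment uses the `"tiny"` model variant
(identical topology, reduced widths) on twenty 320×320 synthetic frames:
300 steps at batch 5, learning rate 4e-3 decayed ×0.25 at step 200, an
8:1 hard-negative ratio, a weight EMA (decay 0.99) whose average is the
final model, and a precise-BN pass (`recalibrate_bn`) that replaces the
lagged running statistics with plain averages over the training images
before inference-mode evaluation. Short from-scratch schedules need these
stabilizers where a long GPU schedule would not; all are exposed as
arguments with conservative defaults. These sizes are stated here once
and used unchanged by the tests.

Three further choices matter for short schedules and are worth naming.
The prediction convolutions use the standard one-stage-head
initialization (weights with standard deviation 0.01 and a background
prior of π = 0.01 on the classification bias), so boxes start on their
anchors and background starts confident. Candidate anchors are restricted
to the pyramid level whose base scale best matches the ground-truth size;
without this, a head can be supervised as positive at several scales and
later detected twice by boxes too dissimilar for NMS to merge. And the
matching cost's localization term uses the decoded predictions (the
published dynamic form); a static anchor-geometry variant is available
(`loc_iou = "anchor"`) but performed worse in the package's experiments,
as did an ignore band around unselected candidates (`ignore_band`), which
left confidently scored but never-regressed duplicates.

## Tracking

A DeepSort-style tracker consumes per-frame detections. Each track carries
a constant-velocity Kalman state over `(cx, cy, aspect, height)` with the
standard DeepSort noise scaling (position std 1/20 of box height, velocity
std 1/160). Association runs as a cascade: confirmed tracks first, ordered
by time since last update, with cost
`(1 − w)·(Mahalanobis distance / gate) + w·(cosine appearance distance)`
gated at the 0.99 χ² quantile (4 dof), solved by a Jonker–Volgenant
shortest-augmenting-path assignment; leftover tracks and detections fall
back to IoU association at threshold 0.3. Lifecycle follows DeepSort:
tracks confirm after 3 consecutive hits, tentative tracks die on their
first miss, confirmed tracks survive `max_age = 30` missed frames. Track
ids are never reused.

The original appearance model is a trained re-identification CNN whose
weights are not published; the package's default embedding is an 8×8×8
joint RGB histogram of the box crop under cosine distance — deterministic,
dependency-free, and discriminative for the synthetic targets, with a
plug-in slot (`embed`) for a learned model. When no pixels are available
(pure detection streams) the appearance term is simply dropped and
association is motion-only.

## Counting

The head center `((xmin+xmax)/2, (ymin+ymax)/2)` is the positional
reference. A counting line is fixed in the frame; each confirmed track's
signed side of the line is tracked frame to frame, and a strict sign flip
in the counted direction (top-to-bottom by default) increments the tally
once per track id. Three deliberate choices guard the count:

* a center exactly on the line keeps its previous side, so boundary jitter
  cannot double-count;
* tracks first observed already past the line are never counted (no
  inferred pre-history);
* one count per id: the tally records animal passages, not crossings, so
  an animal oscillating across the line counts once. A `both` direction
  mode exists for in/out auditing. A consequence inherent to
  tracking-by-detection: an animal lost long enough to be re-issued a new
  id after crossing again would be re-counted.

## The synthetic scene generator

Real corridor footage is not redistributable, so every stage is exercised
on seeded synthetic scenes that emulate the acquisition setting: a fixed
overhead camera over a 2 m corridor that up to four sheep traverse
abreast. Targets enter at the top at staggered times, move downward at
4–9 px/frame with sinusoidal lateral drift, and have head sizes of 36–80 px
in a 640×640 frame; lanes may be drawn deliberately close (occlusion
probability 0.2) so paths overlap. Heads render as soft-shaded ellipses
with a per-track hue and a deterministic speckle texture — enough for the
histogram embedding to be discriminative, which is what the appearance
term needs to be exercised. The generator also produces the exact
ground-truth track table, and a degradation operator turns truth into
realistic detector output (per-box miss probability, Gaussian corner
jitter, Poisson false positives), all driven by one seed.

What the generator does *not* emulate: real fleece texture and lighting,
perspective distortion, motion blur, or correlated detector failures under
severe occlusion. Passing the synthetic suites therefore demonstrates that
the tracking/counting machinery is correct and robust to independent
detection noise — not that the full system reaches any particular accuracy
on farm footage, which requires the original (non-public) dataset and GPU
training.

## Evaluation

COCO-convention metrics: greedy score-ranked one-to-one matching per image,
precision `TP/(TP+FP)·100` (defined as 0 at 0/0), recall `TP/(TP+FN)·100`,
AP as the area under the interpolated PR curve via the 101-point rule, the
0.5:0.95 band as the mean over the ten IoU thresholds, and a small-target
AP restricted to ground truths under 32×32 px² (detections matched to
excluded large ground truths are ignored rather than counted as false
positives; an empty stratum reports `NA`). A frames-per-second utility
(`measure_fps`) implements the throughput definition but is
hardware-dependent and excluded from any accuracy claim.

## Numerical and degenerate-input choices

* Boxes are 0-based half-open floats internally; VOC XML corners (1-based
  inclusive) are converted on read/write. This makes area and IoU
  arithmetic exact and unambiguous.
* NMS ties on score break toward the lower box index (stable order), so
  results are deterministic.
* Batch-norm uses ε = 1e-5 and momentum 0.1; attention convolutions pad
  by 3 so a 7×7 kernel never shrinks a map.
* `exp` in box decoding is clamped (offsets ≤ 10) against overflow from
  untrained heads; decoded boxes are clipped to the frame and empty boxes
  dropped.
* The Kalman filter clamps box height at 1e-3 and symmetrizes the
  covariance after every update to keep it positive-definite.
* Letterboxing uses nearest-neighbour resampling: deterministic, exactly
  invertible for box corners (round-trip within one pixel), and free of
  interpolation-kernel choices.
* "Random clipping" augmentation is a scale-crop of 0.6–1.0 of the frame
  area (no range is published); colour jitter is HSV gains of ±0.1/±0.3/
  ±0.3; a crop that would lose every box is resampled up to 10 times and
  then replaced by the identity.

## Known limitations

* The detector's published accuracy (AP0.5 = 96.11 on the authors'
  dataset) is not reproducible here — it needs the private 17k-image farm
  dataset and GPU-scale training. The package verifies the architecture by
  its deterministic parameter audit and the training loop by CPU-scale
  overfitting instead.
* Dynamic sample matching is a reconstruction from the method's name and
  lineage; its constants are configuration, not transcription.
* The per-layer widths of the backbone and neck are constrained — not
  fully determined — by the published parameter totals; other width
  choices could produce the same totals.
* The appearance embedding is a colour histogram: adequate for hue-coded
  synthetic targets, weak for visually uniform flocks; real deployments
  should plug in a trained re-identification model.
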