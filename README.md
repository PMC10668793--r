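# shssd — lightweight sheep-head detection, tracking and counting

`shssd` is an R implementation of an automated sheep-counting pipeline for
corridor cameras: a lightweight single-shot head detector (**SH-SSD**)
feeds a DeepSort-style multi-object tracker, and a virtual line across the
frame tallies each tracked head once as its center crosses top-to-bottom.
Sheep heads, not bodies, are the detection target: from an overhead camera
they remain visible even when a dense flock occludes itself.

The detector is an SSD-lineage network with three parts:

* a **TA-enhanced MobileNetV3-style backbone** — inverted bottlenecks in
  which squeeze–excite attention is replaced by a *triple attention* block
  (three branches pooling along channel, height and width; each squeezes
  its max/mean maps through a 7×7 conv → batch-norm → sigmoid gate;
  outputs averaged). A TA block costs exactly 300 parameters at any width,
  so attention is added at essentially zero size: 2.98 M (SE) → 2.97 M (TA);
* an **independent feature-branch neck** (no cross-scale fusion): each of
  the three backbone taps (strides 8/16/32) passes through its own
  DW-CBR / SPP / CBR / TAneck stack;
* **decoupled heads** predicting classification and box regression in
  separate convolutional branches, decoded against 3 square anchors per
  cell and pruned by greedy NMS.

Training uses **dynamic sample matching** (a SimOTA-style assignment that
adapts positive anchors to the current predictions), binary cross-entropy
with 3:1 hard-negative mining, and smooth-L1 regression, optimized with
Adam. Every layer — convolution (im2col/GEMM in C++), batch-norm, ReLU6,
attention, SPP — is implemented in the package with exact backward passes
verified against finite differences.

Because the original farm dataset is not public, the package ships a
seeded synthetic corridor-scene generator (frames, PASCAL-VOC XML,
ground-truth track ids, degradable detection streams) so that every stage
is testable end to end. COCO-style evaluation (AP at 0.5 and 0.5:0.95,
small-target AP, precision/recall) is included.

## Worked example

Audit the architecture against its published size, then count a synthetic
scene:

```r
library(shssd)

audit_params("full")
#>   attention backbone    neck  heads   total backbone_M total_M
#> 1        ta  2968088 3316732 158157 6442977       2.97    6.44
#> 2        se  2979566 3316732 158157 6454455       2.98    6.45
#> 3      none  2967488 3316732 158157 6442377       2.97    6.44
```

The `ta` row is the SH-SSD backbone (2.97 M parameters) and complete
detector (6.44 M); the `se` row is the plain MobileNetV3 ablation
(2.98 M backbone); the `none` row shows that removing the 2 attention
blocks drops exactly 600 parameters.

```r
sc <- generate_scene(scene_config(n_tracks = 4, seed = 7))
print(sc)
#> synthetic corridor scene: 4 track(s), 140 frames, 4 downward crossing(s)

rep <- count_scene(sc, "truth")      # tracker + counter on clean detections
cat(rep$total, "counted vs", rep$truth_total, "true crossings\n")
#> 4 counted vs 4 true crossings
```

`count_scene(sc, "degraded")` re-runs the same pipeline on a noisy
detection stream (misses, corner jitter, false positives per the scene
config); `run_pipeline()` swaps in the neural detector itself. A thin
command-line wrapper lives at `inst/scripts/shssd`
(`synth`, `count`, `eval`, `audit-params`, `train` subcommands).

## Training at desk scale

```r
samples <- synth_training_samples(20, 320, seed = 42)
m <- sh_ssd("tiny")                  # same topology, reduced widths
m <- train_shssd(m, samples, steps = 300, batch_size = 5, lr = 4e-3,
                 lr_decay_every = 200, lr_decay_factor = 0.25,
                 neg_ratio = 8, ema_decay = 0.99)
recalibrate_bn(m, samples)           # precise BN before inference
dets <- predict(m, samples[[1]]$image / 255, score_thresh = 0.4)
```

The `"full"` variant accepts the published schedule
(`lr = 5e-4`, `batch_size = 32`, `lr_decay_every` 100 epochs) but needs
GPU-scale compute to train on real data; the package trains the reduced
variant on synthetic frames to verify the matching/loss/decode loop.

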