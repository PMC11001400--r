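---
title: "Methods: MP-FAST hit finding and data reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MP-FAST hit finding and data reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpfast)
```

## The problem

Serial crystallography streams consist overwhelmingly of *miss* frames —
diffuse scattering plus static detector artefacts — interleaved with a few
percent of *hit* frames that carry Bragg peaks. The pipeline in this
package classifies each frame online so misses can be discarded, in four
stages: median-background subtraction, MP-FAST key-point detection, a
region-count descriptor, and a supervised classifier. This vignette
records the model assumptions, parameter choices and numerical conventions
behind each stage, and what the synthetic test bed does and does not
establish.

## Background and artefact reduction

A miss frame is modelled as `background + fixed pattern + counting noise`,
where the first two terms are (locally in time) the same in every frame.
The pixel-wise **median** over a FIFO buffer of the `B` most recent non-hit
frames estimates that common component robustly: unlike the mean, it is
insensitive to a few mislabelled hit frames in the buffer, and hot pixels
and fixed-pattern offsets cancel exactly because they are present in every
buffered frame.

Numerical conventions, chosen where the procedure itself leaves them open:

* **Even buffer sizes**: the median is the arithmetic mean of the two
  central order statistics (the common definition; tested against a
  full-sort reference).
* **Clamping**: residuals are clamped at zero after subtraction. The
  detector thresholds on positive photon counts; negative residuals are
  noise around cancelled background and carry no peak signal.
* **Refresh period**: the estimate is recomputed every `U = 10` buffer
  insertions. A fixed insertion count keeps the online behaviour
  deterministic; `U = Inf` freezes the background after warm-up, which is
  also the configuration under which streamed and offline processing are
  provably identical (and are tested to be).
* **Buffered frames are raw**, not themselves background-subtracted, so
  the estimate never feeds back into its own inputs.

**Warm-up.** Online operation needs misses to fill the buffer before a
background exists, but the classifier that identifies misses operates on
background-subtracted frames. The pipeline bootstraps with a key-point
count heuristic: until the buffer holds `warmup_min_frames` (default 10)
frames, detection runs on raw frames and frames with at most
`miss_count_threshold` key points are routed into the buffer (and labelled
miss). The threshold must sit **above the static artefact floor of raw
frames**: every hot pixel registers as a key point before the first
background estimate exists, so a raw miss frame yields roughly
`hot_pixel_fraction * H * W` key points, not zero. The package default (5)
suits artefact-free streams; the worked examples on the default synthetic
condition (~16 hot pixels per 128x128 frame) use 25. The separation that
makes the heuristic safe is between the artefact floor (common to all
frames) and the additional peaks a hit contributes.

## MP-FAST detection

The detector adapts the FAST segment test from corners to peak apices.
For each interior pixel `p`:

1. **Threshold**: if `I(p) <= tr` (default `tr = 20` counts) the pixel is
   skipped without further checks. The threshold is applied to
   background-subtracted intensities when the full pipeline runs, since
   detection follows the reduction stage.
2. **Cardinal test**: `p` is a candidate iff `I(p)` strictly exceeds the
   intensity at **at least 3 of the 4** cardinal pixels of the radius-3
   FAST circle (pixels 1, 5, 9, 13; offsets (−3,0), (0,+3), (+3,0),
   (0,−3), inherited from FAST's clockwise numbering starting north).
   Strict inequality prevents flat regions from spawning candidates.
3. **Apex refinement**: the key point is the brightest pixel of the 3x3
   neighbourhood around the candidate (candidate included), which places
   multi-pixel peaks on their apex. Ties resolve in favour of the
   candidate, then by smallest row, then smallest column — an arbitrary
   but total order that makes output deterministic. Reading the procedure
   as "max over candidate and its eight neighbours" (rather than the
   neighbours alone) is an interpretation; it is the only reading under
   which a single-pixel peak is its own key point.
4. **Deduplication**: candidates refining to the same apex are merged;
   output is sorted by (row, col).

**Canonical semantics are scan-order independent**: every interior pixel
is tested, so sequential, band-parallel and massively parallel
realizations must produce identical output — `chunked_detect` (horizontal
bands with a 3-pixel halo) is tested for exact equality with whole-frame
detection, and a deliberately naive loop-based oracle is kept alongside
the vectorized implementation. The `sequential_flags` mode reproduces the
CPU fast path in which a processed candidate marks its 3x3 neighbourhood
as checked; it can drop candidates adjacent to an earlier candidate and is
therefore an optional fast path, identical to the canonical mode whenever
peaks are well separated (tested at >= 8 px separation).

**Border policy**: pixels within 3 of any edge are never candidates (the
circle must fit), and a refined apex landing inside that border ring is
dropped so all key points satisfy the same bound.

**Behaviour on broad, bright peaks.** For a Gaussian-profiled peak, any
pixel above `tr` that wins the cardinal test becomes a candidate. When the
profile is wide enough that pixels 2 px from the apex exceed `tr`
(e.g. sigma 1.5 at amplitude 200: the distance-2 shoulder is ~0.41 of the
apex), those shoulders refine to distance-1 neighbours of the apex rather
than the apex itself, so one physical peak yields a small cluster of key
points around its apex. Exact one-key-point-per-peak recovery holds in the
*compact-peak regime* — every pixel beyond 1 px of the apex below
threshold — which covers the package's default peak widths (sigma <= 1 px
at amplitudes up to ~450 counts). The region-count descriptor is mildly
inflated, not broken, by such clusters; the counts remain strongly
class-separating.

## Region-count descriptor

Key points are tallied over a `2 x 4` rectangular tiling (n = 8 regions;
region id = row-major tile index; boundaries are the half-open integer
splits `[floor(t*H/rows), floor((t+1)*H/rows))`). Counts — not positions —
are the feature: they are invariant to where exactly peaks fall within a
region, which is what makes the descriptor robust to the experimental
shifts that degrade position-sensitive features across data sets. A frame
without key points maps to the all-zero vector so that dimensionality is
constant (classifiers need a fixed input width). The 8-way split is a
symmetry choice, and a rectangular grid is the simplest tiling satisfying
it; the geometry is configurable (`descriptor_params`) so radial or other
tilings can be swapped in. Counts are not normalized: at fixed frame size
there is nothing to normalize away, and raw counts keep the miss vector
exactly zero.

## Classifiers

Four supervised models are compared on the descriptors, with these
defaults:

| model | hyperparameters |
|-------|-----------------|
| `mlp` | hidden layers 50/30/20/20, logistic activation, SGD, constant learning rate 0.2, batch 32, up to 1000 epochs, L2 term 1e-5 |
| `svm` | RBF kernel, C = 10 (via e1071/libsvm) |
| `rf`  | Gini impurity, max depth 30, 100 trees (via ranger, seeded) |
| `nb`  | Gaussian, var_smoothing = 1e-9 |

The MLP is implemented in the package (softmax output, cross-entropy loss,
seeded Glorot initialization and minibatch shuffling): no installed R
package provides a multi-hidden-layer perceptron, and the architecture
above is fixed by design. The learning rate and epoch budget are the
package's own choices: plain SGD through four logistic layers converges
slowly, and a constant step of 0.2 with early exit (mean cross-entropy
below 1e-5) trains reliably on count-scale inputs without feature scaling.
A `standardize` switch exists but is off by default — region counts are
already small and commensurable.

Gaussian naive Bayes is likewise implemented directly because the
var-smoothing convention matters here: miss descriptors are identically
zero, so per-class variances vanish and an unsmoothed Gaussian density is
undefined; adding `var_smoothing` times the largest feature variance to
every variance keeps the model defined on exactly the degenerate inputs
this pipeline produces.

Evaluation uses precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their
harmonic mean F1, and accuracy, reported as percentages, with **0 by
convention** for zero denominators so degenerate folds stay defined.
Multi-class problems (the optional five-class taxonomy) report
macro-averaged one-vs-rest metrics — a declared choice, since a single
summary number requires *some* averaging rule. Cross-data-set evaluation
trains on one full corpus and tests on another; the diagonal uses a
seeded, stratified 80/20 held-out split of the same corpus. Grid-search
tuning is an exhaustive loop over candidate specifications with stratified
k-fold cross-validation, ties broken by grid order, and a hard error when
a class cannot reach every fold.

## The synthetic test bed

`sim_params()` defines the study conditions; its defaults are fixed once:
256x256 frames, Poisson background of 1 count/pixel, a smooth cosine-field
fixed pattern of amplitude 10 counts, hot pixels at fraction 0.001 set to
500 counts, and per hit frame 5-20 planted peaks with apex amplitudes of
100-300 counts, widths sigma in [0, 1] px (single-pixel through ~3x3
footprints, the single-/multiple-pixel peak taxonomy), and a minimum apex
separation of 8 px. Peaks are discretized isotropic Gaussians truncated at
3 sigma with the apex carrying the drawn amplitude exactly — a standard
stand-in profile whose virtue here is that ground-truth apices are exact,
so detector tests have a sharp oracle. Poisson resampling of the peak
profile itself is available (`peak_poisson = TRUE`) but off by default for
the same reason. Placement is rejection sampling with a 1000-attempt cap
per peak, failing deterministically rather than hanging. Every frame draws
its randomness from a sub-seed derived from the run seed and frame index,
so stacks are bit-reproducible and any single frame can be regenerated in
isolation.

What the generator **does not** emulate: Ewald-sphere geometry, unit-cell
or space-group structure in peak positions (apices are uniform), panel
gaps and multi-module detector geometry, per-pixel gain variation, beam
intensity jitter, and the long-tailed jet-scattering backgrounds of real
runs. Passing tests therefore establish the pipeline's *algorithmic*
contracts — detector semantics, background cancellation, descriptor
arithmetic, classifier separability under the stated noise model — not
classification accuracy on facility data.

The optional five-class mode (Blank / No Crystal / Weak / Good / Strong)
realizes the classes purely as planted-peak count bands
(0 / 1-2 / 3-8 / 9-20 / 21-40); it exercises the multi-class plumbing and
claims no fidelity to the class definitions of real five-class corpora.

## Problem sizes used by the tests

The acceptance-style test suite and `scripts/acceptance.R` use: 500 random
128x128 frames for detector-vs-oracle equality across thresholds
{0, 20, 50}; 200 random buffers of 1-100 frames for the median oracle;
200 (tests) / 100 (script) hit frames at the default 256x256 condition for
apex recall and false positives, with the background estimated from 100
miss frames; 100 miss frames for sparsity; corpora of 500 + 500 (tests) or
400 + 400 (script) frames at 128x128 for classification, with a seeded
stratified 80/20 split; a shifted condition (background rate 4, 3-10
peaks, different fixed pattern) of 500/400 frames for cross-condition
transfer; and a 300-frame stream at a 3.4% hit rate for the reduction
ratio. These sizes give stable percentages while keeping the whole suite
in the low minutes on one CPU.

## Known limitations

* The detector reports apex pixels only — no sub-pixel centroiding, peak
  integration or SNR estimation, and no radial background statistics.
* Bright peaks wider than the compact-peak regime produce key-point
  clusters (see above); applications needing one key point per physical
  peak at such widths would need cluster merging beyond 3x3 dedup.
* The count descriptor discards all intensity information; two frames
  with equal counts per region are indistinguishable downstream.
* Hardware realizations (multi-threading, GPU, FPGA) are out of scope;
  `chunked_detect` preserves the region-splitting contract in
  single-process form so that parallel ports can be validated against it.
* Frame stacks travel as RDS containers plus plain CSV for peaks and
  features; facility-native container formats and multi-panel geometry
  are not handled.
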