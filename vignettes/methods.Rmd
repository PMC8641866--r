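---
title: "Methods: retinex enhancement and reverse-attention vessel segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retinex enhancement and reverse-attention vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented by **rfarn**, the choices
made where the design was genuinely open, and what the synthetic test bed
does and does not demonstrate.

## 1. Image enhancement

### The retinex model

A fundus photograph is modelled as the pixel-wise product of a reflectance
component (the tissue) and an incident illumination component. Estimating
and removing the illumination both corrects the uneven brightness typical
of fundus cameras and raises vessel contrast. The single-scale retinex
(SSR) works in the log domain:

$$R_\sigma(x, y) = \log(P(x, y) + \varepsilon) - \log\big((G_\sigma \ast P)(x, y) + \varepsilon\big),$$

where $G_\sigma$ is a unit-sum Gaussian surround. Small $\sigma$ preserves
local detail at the cost of colour fidelity; large $\sigma$ the reverse.
The multiscale retinex (MSR) therefore averages SSR maps over several
scales with weights $W_m$, and the colour restoration gain

$$C_i = \beta\,\big[\log(\alpha P_i + \varepsilon) - \log(\textstyle\sum_j P_j + \varepsilon)\big]$$

re-weights each channel by its share of the local colour, preventing the
channel-wise log processing from washing out chromatic information.

Parameter choices (all exposed in `msrcr_config()`):

* **Scales and weights.** $M = 3$, $\sigma = (15, 80, 250)$ pixels with
  equal weights — the canonical small/medium/large surround triple of the
  multiscale-retinex literature, balancing detail, fidelity and dynamic-
  range compression.
* **Colour restoration.** $\alpha = 125$, $\beta = 46$, the standard gains
  for 8-bit imagery.
* **Log-domain floor.** $\varepsilon = 1.0$ inside every logarithm, so the
  dark background outside the field of view can never produce $\log 0$.
* **Gaussian surround.** Truncated separable kernel of half-width
  $\lceil 3\sigma \rceil$ with reflect-101 borders; this matches a dense
  brute-force convolution oracle to $10^{-6}$ in the tests.
* **Output rescaling.** After the reflectance–gain product, each channel is
  affinely mapped from mean $\pm\,2$ sd to $[0, 255]$ and clipped
  (`rescale = "meanstd"`). A global min–max map is selectable, but a single
  extreme pixel then crushes the usable contrast, which is why the clipped
  policy is the default.

### Grayscale conversion and normalisation

The enhanced RGB image is reduced to one channel with the luma weighting
$I_{gray} = 0.299R + 0.587G + 0.114B$, under which red, green and blue
contribute 29.9 %, 58.7 % and 11.4 %. Green dominating suits vessel
imagery: vessels are darkest, and the background cleanest, in the green
band. An alternative reading of the design — feeding a more strongly
G-dominant blend — is possible, but the explicit weighted formula is the
one implemented, and the weighting is a single place to change.

Pixel intensities are then Z-scored, $(I - \mu)/\sigma$, using the **pooled
statistics of the training split only** (population standard deviation).
The statistics are frozen and re-applied to held-out images, avoiding
test-set leakage; per-image statistics would also subtly change a stitched
probability map between runs with different test sets. Finally each image
is min–max mapped to $[0, 255]$, which the network consumes divided by 255.
Degenerate inputs (constant images) raise classed errors rather than
producing NaNs.

## 2. The segmentation network

`rfarn_init()` builds the reverse fusion attention residual network: four
residual encoder stages fed by a side-input pyramid, reverse channel
attention on the skip connections, three decoder stages, reverse spatial
attention between decoding steps, and a sigmoid head. The full topology is
described in the README; here are the open points and how they were fixed:

* **Channel widths.** Stage widths double from `base_channels`
  (default 32 → 32/64/128/256). The tests and examples use reduced widths
  (8 or 4); width only scales capacity, not topology.
* **Side-input fusion.** Each pyramid level passes through a 3×3
  convolution to the stage's input width and is added to the incoming
  pooled features; the first stage consumes its side input directly. This
  is the minimal fusion consistent with one side arrow per stage.
* **Residual block.** conv → BN → ReLU ordering (standard residual
  practice), an identity shortcut when channel counts match and a 1×1
  projection otherwise; the block output is the sum of the dilated branch
  and the shortcut.
* **Channel affinity axis.** The softmax in the channel attention is taken
  over the first index, making every column of the affinity matrix sum
  to 1; the axis is asserted in the tests.
* **The parametric gate.** The "optimal" attention matrix is obtained from
  the sigmoid-activated affinity through a learnable per-channel scalar
  gate initialised at 1 — the minimal parametric choice consistent with a
  learned re-scaling.
* **Attention placement.** One RCAM per adjacent encoder pair (its output
  *replaces* the plain skip tensor) and one RSAM after each decoder stage.
* **Spatial attention normalisation.** The gated decoder map is normalised
  with a softmax over all spatial positions, independently per channel;
  each slice sums to 1.
* **Initialisation.** Kaiming-uniform weights, zero biases, unit BN scale,
  all under a caller-supplied seed.

The forward/backward graph is a reverse-mode autodiff tape over dense
arrays with C++ kernels for convolution, transposed convolution and
pooling. Batch normalisation uses batch statistics (population variance)
during training, updating running statistics with momentum 0.1, and the
frozen running statistics at inference, which makes inference deterministic
for fixed weights. The whole graph is verified against central finite
differences in the test suite.

## 3. Training and inference protocol

Training follows the published recipe: Adam with $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$, learning rate 0.001, weight decay
0.0005, batch size 32, and a budget of 200 epochs, on randomly extracted
48×48 patches. Points the recipe leaves open:

* **Patches per epoch** defaults to 4096; the desk-scale examples use 256.
* **Plateau schedule.** Patience 10 epochs, factor 0.5, floor $10^{-6}$,
  driven by a held-out validation loss (10 % of each epoch's patches) —
  the training loss itself would make the plateau criterion noisier.
* **FOV constraint.** Sampled patches must have at least half their pixels
  inside the field of view, so training is not dominated by the black
  camera border.
* **NaN handling.** A non-finite loss aborts with a classed error rather
  than continuing silently; gradient clipping is off by default.

At test time a 48×48 window slides with stride 5 (both configurable in
`patch_spec()`); corners sit at multiples of the stride plus one final
corner flush with the far edge so every pixel is covered by at least one
window without relying on padding for real pixels. If an image is smaller
than the window, the patch is zero-filled. Overlapping predictions are
**averaged** — unlike last-write-wins, averaging is order-independent and
suppresses seam artifacts — and extraction followed by stitching is an
exact inverse on full-coverage inputs.

## 4. Evaluation

Predictions are thresholded at 0.49 with a strict `>` (probabilities stay
in floating point until this point; the 8-bit level 125/255 ≈ 0.4902 sits
just above the threshold). Confusion counts are restricted to the
field-of-view mask — sensitivity and specificity are jointly meaningless if
the trivial background outside the camera aperture is counted. Ratios with
zero denominators are reported as flagged NaN, never silently 0, so a
vessel-free tile cannot inflate specificity. Across a test set, counts are
summed (micro-average) for the headline metrics and pooled pixels give the
headline AUC; a per-image table is also emitted since per-image mean/sd is
the conventional reporting format. ROC and PR curves sweep all distinct
probability values and integrate by the trapezoid rule; the ROC-AUC is
checked against the pairwise rank-comparison (Mann–Whitney) statistic in
the tests.

## 5. The synthetic test bed

`make_synth_dataset()` renders branching random-walk vessel trees
(angular-jitter steps, children spawned with a per-step probability, width
decaying per branch level) into 128×128 fundus-like images: a reddish
background (R > G > B), a radial illumination fall-off (centre-to-edge
ratio 1.6), vessels darkening mainly the green channel (drop 55 with a
weaker red component), additive Gaussian noise (sd 8) and a circular field
of view. Every sample is a pure function of (configuration, index). The
defaults were chosen once as a plausible desk-scale emulation of the
properties the enhancement stage targets — uneven illumination, modest
vessel contrast, noise — with a vessel load of roughly 6–17 % of the frame,
comparable to clinical vessel density.

What passing tests on this bed shows: every stage runs end to end, learns
(a reduced network overfits a single patch, and reaches F1 ≥ 0.7 /
ROC-AUC ≥ 0.9 on held-out renders), and is reproducible seed-to-seed. What
it does not show: performance on real fundus photographs. The generator has
no pathology (haemorrhages, exudates), no optic disc or macula appearance
model, no inter-image colour variation, and vessel geometry far simpler
than a real vascular tree; clinical-scale accuracy claims require the
public datasets and a full-size training budget (the 200-epoch, batch-32,
width-32 configuration is available but is deliberately not exercised by
the tests).

Problem sizes used by the test suite and examples — 128×128 synthetic
images, width-8 networks, 256 patches per epoch for up to 30 epochs — were
chosen as the package's desk-scale defaults; all of them scale up by
configuration only.

## 6. Known limitations

* Single-threaded CPU implementation; practical for patch-scale research
  and testing, not for training the full-width model on clinical datasets.
* GIF and JPG rasters (the label format of one public dataset and the
  image format of another) have no reader in the supported stack; loaders
  accept any of PNG/TIFF/PPM for every role instead.
* STARE evaluation uses the first observer's labels; the second observer is
  not modelled.
* No data augmentation (rotations/flips) — not part of the implemented
  recipe.
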