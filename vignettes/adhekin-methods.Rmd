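---
title: "Methods: label-free single-cell adhesion classification with adhekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free single-cell adhesion classification with adhekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and the problem

A resonant waveguide grating (RWG) biosensor reads out, for every 25 µm
pixel of a 2 × 2 mm sensor, the shift (in picometers) of the resonantly
incoupled wavelength. That shift tracks the refractive index within
~100–150 nm of the surface and therefore the amount of cell material
adhering above the pixel. A plate reader of this kind images 12 wells of
80 × 80 px each, tiled 3 × 4 into a `(T, 240, 320)` video mosaic, at a
scan every few seconds. Because a spreading cell occupies only about 3 × 3
biosensor pixels, single-cell work at this resolution needs help from a
higher-resolution modality: each well is also photographed with a
phase-contrast microscope, segmented there (externally, e.g. with a
Cellpose-style network, or by hand), and the segments are projected back
onto the sensor grid.

`adhekin` implements the full evaluation chain: preprocessing of the
biosensor video, registration of the two imaging planes, single-cell
extraction by three strategies, dataset assembly, four small
spatio-temporal neural classifiers, and the segmentation/classification
metrics. A synthetic experiment generator with complete ground truth makes
every stage testable without instrument data.

## Synthetic experiments

The generator (`synthetic_config()`, `generate_experiment()`) emulates the
statistical structure the pipeline assumes:

* **Kinetics.** Each cell follows a saturating exponential
  `A (1 − exp(−k t))` after a per-cell onset jitter. This matches the
  monotone, saturating adhesion curves of real recordings without
  committing to a mechanistic model. Defaults: three types with amplitudes
  150/300/450 pm and rates 0.04/0.065/0.09 min⁻¹, onset jitter up to
  2 min. The amplitudes are spaced many noise standard deviations apart so
  that class recovery is a property of the pipeline, not of a lucky seed.
* **Footprint.** An isotropic Gaussian with σ = 1.3 biosensor px. With a
  150 pm amplitude the 75 pm superlevel set covers exactly a 3 × 3 pixel
  block, the footprint reported for real cells.
* **Noise and drift.** Additive Gaussian sensor noise (default σ = 6 pm)
  and a global per-frame offset drawn from ±5 pm (thermal/optical drift);
  the video is quantized to the instrument's 0.25 pm scan step.
* **Timeline.** Baseline frames, then one inter-frame gap equal to the
  pipetting pause (default 1800 s), then adhesion frames every 135 s —
  40 frames spanning 90 min at desk scale (real recordings scan every ~3 s;
  the pipeline is agnostic to the frame interval).
* **Boundary artifacts.** A fraction (default 15 %) of the outer two-pixel
  ring of each well carries a static offset of 10–30 × 10³ pm, emulating
  the huge, time-constant resonance defects where the sensor meets the
  well wall. These are what the 3σ outlier mask is for.
* **Microscope plane.** Each well gets a grayscale pseudo-phase-contrast
  image and a ground-truth label mask; cells are ellipses (mild axis
  jitter) centered at `scale · centroid + translation` with the true
  similarity transform known. Default scale 10 (2.5 µm microscope pixels).

What the generator does **not** emulate: cell migration and detachment,
multi-cell superposition on one sensor pixel, optical point-spread
effects, spatially correlated noise, or the shape complexity of real
phase-contrast images. Green tests on synthetic data therefore certify the
algorithmic chain (geometry, bookkeeping, statistics, learnability), not
instrument-grade performance on real cultures.

## Preprocessing

1. **Well splitting** slices the mosaic into 80 × 80 blocks.
2. **Adhesion-start detection** finds the largest timeline gap exceeding
   `gap_factor` (default 10) × the median scan interval and trims
   everything before it. Pipetting pauses are minutes against seconds-scale
   scans, so the factor is uncritical.
3. **Offset correction** subtracts the first trimmed frame per pixel.
4. **Outlier masking** excludes pixels outside mean ± 3σ. The statistics
   are computed on the *raw first frame* (stored by `offset_correct()`),
   not on the adhesion reference image: boundary artifacts are static and
   enormous (10³–10⁶ pm), so they dominate the raw frame, while adhered
   cells (10² pm) appear only later. Computing the 3σ boundary on an
   adhesion-phase reference would flag the cells themselves as outliers on
   clean wells — the brightest pixels of an otherwise flat image are
   always ±3σ outliers — which is why the raw frame is the right place for
   this rule.
5. **Background correction** estimates, per frame, the mean shift over a
   pseudorandomly selected set of background pixels and subtracts it from
   the whole frame. Candidates must lie below the 75 pm foreground
   threshold on the kinetic image (the per-pixel maximum over time, robust
   to late adhesion), at least 2 px from any foreground pixel and from
   each other, and are drawn with a Gaussian center weighting (σ = 20 px)
   to avoid the well periphery. Per-frame (rather than single-scalar)
   subtraction is used because drift is temporal. After correction the
   background mean of every frame is zero to numerical precision.

## Registration

The two planes are related by `m = s·b + t` — scale plus translation, no
rotation or shear (the instruments share an orientation). From N ≥ 2
user-picked point pairs, the scale is the mean over all N(N−1)/2 unordered
pairs of the microscope/biosensor distance ratio, and the translation is
the mean of `m − s·b`. All-pairs averaging is the symmetric choice among
the pairing schemes consistent with a distance-ratio estimate; with exact
correspondences any scheme is exact, and the all-pairs mean has the lower
variance under noise. With one pair, the nominal scale from device
metadata (microscope µm/px against the sensor's 25 µm pitch) is kept and
only the translation is estimated.

Masks are projected by inverse-mapping every microscope pixel center; a
biosensor pixel belongs to a cell's *cover* if at least one mapped center
lands in its unit square. This is the simplest rule consistent with
"pixels intersecting the mask" and is exactly reproducible; a
fractional-area threshold would need a rasterization convention of its
own. Where two cells cover one pixel, both keep it in their pixel sets and
the single-valued mask sides with the larger contributor.

Coordinates everywhere are `(row, col)`, 1-based, pixel centers at integer
positions, on both planes — one convention for the whole package.

## Single-cell extraction

Three strategies produce per-cell biosensor pixel sets: **M** (cover of
manually annotated masks), **P** (cover of predicted masks — same code
path, different mask source), and **W** (marker-controlled watershed on
the kinetic image: local maxima in `[lower, upper]` thresholds seed a
priority-flood of the negated Euclidean distance transform of the 75 pm
foreground). Candidates are filtered by area, maximum adhesion, and
centroid distance from the well border (default ≥ 4 px so that the crop
fits). Each survivor yields a `(t, 8, 8)` sample: rows r−3…r+4, columns
c−3…c+4 (centroid at crop index (4, 4)), truncated to the requested
timespan. The full 8 × 8 neighborhood is kept — pixels outside the cell's
own set are *not* zeroed, since the classifiers are meant to see the local
context as exported.

## Datasets and standardization

Labelled samples are split 64–16.5–16.5 % into train/validation/test,
stratified per class with largest-remainder rounding (the ratios cannot be
exact for every count; largest-remainder keeps each split within one
sample of its target per class). Class imbalance is countered by
oversampling every class to the majority count with random repeats.
Per-pixel standardization statistics — mean and sample (n−1) standard
deviation for every (frame, row, col) — are computed with Welford's online
algorithm over the *training split only* (the leakage-safe reading of
"precomputed standardization factors") and applied as
`(x − µ)/max(σ, ε)` with ε = 10⁻⁶ guarding constant border pixels. The
30/60/90-minute dataset variants share samples and differ only in the
frame-prefix length; each variant gets its own statistics.

## Classifiers

Four architectures map `(t, 8, 8)` standardized samples to class
probabilities. Shared vocabulary: 3 × 3 × 3 convolutions (the temporal
extent of the kernel matches the spatial one), ReLU, dropout (0.2), layer
normalization (per-sample over all features, per-channel affine — chosen
so the parameter count is independent of t), max pooling halving the
spatial grid 8 → 4 → 2, an adaptive temporal average pool to 4 frames, and
a head of two fully connected layers (hidden 64) ending in a softmax.

* **CNN** — two blocks with 8 and 16 channels; the first pool also halves
  time.
* **ResNet** — two stages of two basic (non-bottleneck) blocks with
  channel plans (8, 16) and (16, 32); 1 × 1 × 1 projections on
  channel-changing skips; pooling as in the CNN.
* **DenseNet** — a stem to 8 channels, then two dense blocks of 4 layers
  with growth 8 (every layer sees the concatenation of all previous
  feature maps), each followed by a 1 × 1 × 1 transition halving the
  channels and a pool.
* **CNN-LSTM** — three conv blocks (8, 16, 32 channels) with spatial-only
  pooling down to 1 × 1 per frame, then a 3-layer LSTM of hidden size 256
  whose final hidden state feeds the head.

Unspecified hyperparameters (dropout rate, head width, DenseNet
depth/growth, temporal pool target, batch size, early-stop patience) are
exposed in `model_config()` / `train_config()` with the defaults above.
Training uses Adam (lr 10⁻⁴, weight decay 10⁻⁵), cross-entropy, at most
250 epochs with early stopping on validation loss (patience 25) and
restoration of the best-validation weights; `cross_validate()` runs
5-fold stratified cross-validation on the train+validation pool with the
test set held out. All of this is implemented in an in-package
matrix-multiply (im2col) engine with hand-derived backpropagation —
verified against central finite differences to ~10⁻⁷ relative error —
because the surrounding R environment provides no spatio-temporal
network stack; the engine is deliberately minimal (no autograd, five
tensor layers and an LSTM) and single-threaded deterministic given seeds.

## Evaluation

Segmentation: predicted and truth cells are matched greedily by descending
pixel intersection, one-to-one; a truth cell is *detected* if its match
reaches IoU ≥ 0.3 (the matching rule is not dictated by the source
material; the threshold is exposed). Detection error DE is the fraction of
undetected truth cells. The Dice-based score DS is reported as
1 − mean(Dice) over matched pairs — a *dissimilarity*, so that like DE,
lower is better; the raw mean Dice is returned alongside so either
convention is recoverable. DS on the microscope plane (DS_m) and on the
biosensor plane (DS_b) use the same code with different pixel sets.

Classification: accuracy, macro F1, macro one-vs-rest AUC (rank form) and
macro average precision (AUC-PR), each verified in the tests against
brute-force pair/threshold enumeration; support-weighted variants are
emitted as well because class imbalance inflates the unweighted AUC.
Row-normalized confusion matrices, per-class PR curves, and an exact
(O(n²)) t-SNE embedding of the probability vectors (perplexity binary
search, early exaggeration 12 for 100 iterations, momentum 0.5 → 0.8)
complete the report. The t-SNE is implemented in-package and is
deterministic per seed.

## Numerical and storage choices

* Wavelength-shift TIFFs use a fixed-quantum integer codec
  (step 2⁻¹² pm ≈ 0.00024 pm, range ±262 144 pm, 32-bit samples): values
  on the instrument's 0.25 pm grid round-trip bit-exactly, and any written
  file re-reads and re-writes to identical bytes. Masks are 16-bit
  integer TIFFs; float images are rejected as masks.
* Local-maxima plateau ties break in (row, col) lexicographic order,
  keeping the first pixel.
* Watershed flooding order is by decreasing distance-transform value with
  a deterministic heap, so results are reproducible.
* Degenerate inputs: zero standard deviation disables outlier masking;
  σ = 0 pixels standardize through the ε floor; empty masks, empty
  candidate lists and empty wells flow through as empty results rather
  than errors, except where the operation is meaningless (background
  correction without background pixels, matching without truth cells).

## Problem sizes in the tests

The test-suite experiments are sized for a laptop-class run: segmentation
oracles use 6 wells × 20 cells (noise-free); drift removal uses one noisy
well with 100 background pixels; classifier recovery uses 3 types ×
200 samples of 40 frames with a short (≤ 3 epoch, lr 10⁻³) training
schedule, which the separable defaults saturate within the first epoch;
the timespan comparison retrains the CNN on 14-frame and 40-frame
prefixes of types that differ only in adhesion onset. These sizes are the
package's own scaled-down study conditions; the defaults in
`train_config()` remain the full regime.

## Known limitations

* The fallback threshold segmenter is a convenience for synthetic and
  clean images, not a substitute for a trained segmentation network on
  real phase-contrast data.
* Heavily overlapping cells are kept as single labels (mask-side
  convention); no multi-cell deconvolution is attempted.
* The watershed strategy inherits the known bias toward enlarged regions
  for strongly adherent cells; it is evaluated, not corrected.
* The neural engine favors clarity and determinism over speed; it is
  adequate for the (t, 8, 8) sample geometry, not a general-purpose
  training stack.
* No cell tracking across frames; samples are spatially anchored crops.
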