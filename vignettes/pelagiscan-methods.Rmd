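---
title: "Spatial-spectral fish classification: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-spectral fish classification: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pelagic fish species landed together — anchoveta, common sardine, hake,
mote sculpin, pampanito — can look alike in size, shape and texture, which
makes visual catch-control error-prone. A VIS-NIR hyperspectral camera sees
more than shape: every pixel carries a full reflectance spectrum, and skin,
scales and mucus give each species a characteristic spectral "fingerprint".
`pelagiscan` implements a complete classification pipeline over such data:
calibration, per-fish segmentation, spectral-signature extraction, RGB
rendering, augmentation, a two-channel convolutional classifier with
classical baselines, and cross-validated evaluation.

## Pipeline stages and their models

### Reflectance calibration

A push-broom line scanner records raw digital counts `A(i, j, c)`. Dividing
by a white-standard frame `R(j, c)` (a near-perfect diffuse reflector
captured under the same illumination) converts counts to reflectance:

    S(i, j, c) = A(i, j, c) / R(j, c)

The reference varies by cross-track pixel and band (push-broom geometry) and
is broadcast along the scan axis. Two numerical choices are ours: reference
entries below `1e-6` of the frame maximum are floored before dividing (the
formula is silent about dead pixels), and the result is clipped to `[0, 1]`
by default — a 99% standard means true reflectance can slightly exceed 1,
so clipping is configurable off for diagnostics.

### Segmentation

Fish lie separated on a uniform board, so one high-contrast band suffices
for a binary mask. Practitioners usually pick a high-contrast wavelength by
eye; here the band is chosen automatically as the slice maximizing Otsu's
between-class variance, which honors "high contrast" while removing the
manual step (a `band` argument overrides it). Thresholding takes the minority class as
foreground, a 3x3 morphological closing bridges scale-level gaps
(configurable off), and 8-connected components of at least `min_area = 50`
pixels become per-fish masks, ordered left to right. Bounding boxes are
0-based and half-open — a convention pinned deliberately so that widths are
`col_max - col_min` and crops are unambiguous; band indices, by contrast,
are 1-based as everywhere in R.

### Spectral signatures

The whole-body signature averages reflectance over the mask pixels per
band. The averaging region is the fish mask, not the full crop: averaging
the whole `N x M` window would let board pixels contaminate the curve;
`include_background = TRUE` averages the literal full window instead, for
comparison. RoI signatures average `P` pixels drawn uniformly without
replacement inside the mask; `R` such draws give an `R x Lc'` array per
fish, and redrawing RoIs is the spectral half of data augmentation. `R`,
`P` and the reduction rule are free parameters; we default to `R = 1`,
`P = 256` and linear interpolation onto `Lc' = 200` evenly spaced
wavelengths. `Lc' = 200` is pinned by the
architecture: after two 2x poolings and 2 final filters the spectral
channel must flatten to exactly 100 features. Each RoI uses its own RNG
substream (subseeds drawn once from the master seed), so RoI `r` is
reproducible regardless of `R`.

### RGB rendering

An RGB camera is emulated in two linear steps: a projection matrix averages
the hyperspectral bands whose centers fall into each of 33 camera channels
(10 nm wide, centered 400-720 nm; intervals are half-open), then an
`LRGB x 3` spectral-sensitivity matrix mixes the channels into R, G and B.
The bundled sensitivity table is a synthetic stand-in with Gaussian channel
responses (B, G, R peaking at 460, 530, 600 nm, sigma 30 nm) shipped as
`inst/extdata/canon_like_33band.csv`; any CSV with columns
`wavelength_nm, R, G, B` is accepted, so measured curves drop in directly.
8-bit quantization divides by the image's maximum linear value
(deterministic and fixture-friendly); a fixed-gain mode exists for
cross-image comparability. No gamma or white balance: the pipeline is
deliberately linear end to end.

### Augmentation and balancing

Images are standardized to 256x256 on a white background (whiteout happens
before the bilinear resize; aspect ratio is not preserved, so an elongated
line-scan crop is simply stretched to the square frame). Augmentation applies horizontal and
vertical flips with probability 0.5 each, rotation uniform in +/-25
degrees, and translation uniform in +/-10% per axis, filling exposed
regions with white. The rotation/translation ranges are deliberately mild
and silhouette-preserving. Balancing keeps every
provided sample and cycles through a class's originals, pairing each fresh
spatial transform with a fresh RoI signature from the same source fish;
per class exactly `target - provided` samples are added (58 provided
becomes 942 augmented at a target of 1000). Because a 5000-sample set of
256x256x3 doubles would occupy ~8 GB, images live as 8-bit raw vectors and
can be kept lazy (recipe + seed) and materialized on demand; redraws use a
per-fish bank of up to `bank_px = 1024` masked-pixel spectra rather than
re-opening the source cube.

### The two-channel CNN

Both channels follow conv -> batch-norm -> ReLU -> 2x max-pool -> dropout,
twice. The spatial channel (3x3 kernels, 8 then 16 filters) flattens a
256x256x3 image to 64*64*16 = 65,536 features; the spectral channel
(length-5 kernels, 4 then 2 filters) flattens a length-200 signature to
50*2 = 100 features. Filter counts, kernel sizes and the 64-unit dense head
are pinned so that those two characteristic flatten sizes hold exactly; any
other geometry with the same flatten sizes would be an equally consistent
choice. The fused model
concatenates both vectors (65,636) before the dense softmax head; dropout
is 0.25 throughout. Training is plain SGD (learning rate 0.05, batch 32,
cross-entropy) with up to 4000 epochs, early stopping after 50 epochs
without validation-loss improvement on a stratified 33% split, and
best-weight restoration. Weights are He-initialized from the training seed,
images are scaled to `[0, 1]`, signatures enter as reflectance. One
engineering choice: the batch-norm running moments are seeded from the
first batch instead of decaying from a cold start, so validation-based
early stopping is meaningful from epoch 1; inference always uses the
running moments and no dropout, making prediction deterministic.

The conv/batch-norm/pool kernels are compiled (im2col + BLAS matrix
products, with batch-norm, ReLU and pooling fused into one pass) because a
CPU-only training loop in plain R would dominate the package's run time;
gradients of every kernel are verified against numerical differentiation
in the unit tests.

### Baselines

Linear SVMs (one-vs-rest over binary machines, `C = 1`, no kernel tuning)
on five feature variants: z-scored signatures; raw `[0, 1]` pixels
(196,608 wide); HOG (8 unsigned orientation bins, 16x16 cells, 4x4-cell
blocks, one-cell stride, L2-Hys — 21,632 features at 256x256); and the two
concatenations. The one-vs-rest reduction and the z-scoring of spectral
features (with training moments reused on held-out data) are pinned for
reproducibility; pixel and HOG features are not standardized.

### Evaluation

Metrics come from one-vs-rest reductions of the confusion matrix, reported
in percent: per-class accuracy, precision, recall, F1, their
support-weighted averages, and global accuracy. Weighted averaging is the
aggregation under which overall accuracy equals weighted recall exactly —
the algebraic identity behind identical Accuracy and Recall columns in
weighted reporting — and the tests assert the three-way identity with the
mean zero-one loss. Cross-validation is stratified at the sample level
(matching the 4000/1000 per-fold arithmetic of a 5000-sample set at
k = 5); a `group_by_source` mode instead keeps all augmented descendants
of one physical fish in a single fold, a leakage-safe variant worth
reporting alongside, since sample-level folds let augmented copies of one
fish straddle the train/test boundary. Model comparison uses the two-sided
Wilcoxon signed-rank test on per-sample zero-one losses paired by sample:
with only five folds as pairs a two-sided p below 0.05 is unreachable, so
per-sample pairing is the only consistent reading. Zero differences are
dropped; up to 25 effective pairs the p-value comes from the exact
sign-flip distribution (computed by convolution, midranks kept integral by
doubling); beyond that a normal approximation with tie and continuity
correction is used, matching `wilcox.test` in the no-exact regime.

## The synthetic study conditions

The real fish cubes are available only on request, so the package ships a
generator that emulates the acquisition: fish-shaped objects (tapered
ellipses with species-specific length, aspect and taper) on a flat board
of reflectance 0.15, each species carrying a smooth spectral template —
a shared baseline plus species-specific Gaussian peaks and valleys on
400-1000 nm, one species with a pronounced feature near 600 nm. Three of
the five species share a near-identical silhouette while two differ, so
shape alone cannot separate the full class set but spectra can — the
regime in which the spectral channel earns its keep. A single knob `delta`
in `[0, 1]` scales the inter-species spectral differences (pairwise
template distance is exactly linear in it); `delta = 0` makes spectra
uninformative. Noise is multiplicative lognormal (sigma 0.02) plus a
smooth low-frequency surface texture in `[0.8, 1.2]` — both multiplicative
so reflectance stays positive. The texture
lives in body-normalized coordinates, i.e. every fish sees the same
texture statistics relative to its own body: a scene-scale field would
make the dispersion of RoI-mean levels depend on body size, and body size
is species-specific, so spectrally identical species (`delta = 0`) would
become partially separable through a channel that is supposed to carry no
class signal. The board itself is perfectly flat. Raw counts
are constructed as reflectance times a synthetic lamp-plus-vignetting
reference frame, so calibration inverts the construction exactly up to the
injected noise — a property the tests assert at tolerance 1e-6 in the
noise-free case.

What the generator does not emulate: real scale texture, fins and
body-interior reflectance gradients, specular highlights, overlapping or
touching fish, dark current, and the actual measured species curves (they
are not tabulated anywhere we could copy). Passing tests therefore
demonstrate that the pipeline's machinery is correct and that the
classifier recovers class structure under these conditions — not that any
real-data accuracy is reproduced. Real-data behaviour is mirrored only
qualitatively: on a 3-species same-silhouette regime the
fused model must match or beat spectral-only, both must beat spatial-only,
and the fused-vs-spatial loss difference must be significant under the
Wilcoxon pairing.

## Problem sizes used by the test suite

The default scene is 400x600 pixels by 281 bands; the tests scale the
raster and band count down (scenes around 200x300 by 40-120 bands, fish at
0.35-0.5 scale, `Lc' = 40-100`) and train for 10-15 epochs — sizes chosen
so the whole suite, including two full CNN experiments and a
5000-sample balancing run, completes on a single CPU in well under half an
hour. Epoch budgets in tests stay within the early-stopping protocol
(patience never exceeds the budget), and every randomized stage is driven
by an explicit seed, so reruns are byte-identical.

## Known limitations

- The CNN trains on CPU with batch 32 and no momentum; wall-clock cost therefore grows quickly with image
  count, and the 4000-epoch default budget is only sensible for the real
  full-scale experiment.
- The filter geometry satisfying the two characteristic flatten sizes is
  not unique; ours is one consistent choice, exposed entirely in
  `cnn_config()`.
- `segment_fish` assumes non-overlapping fish; touching silhouettes merge
  into one component by design (no instance splitting).
- The Wilcoxon comparison treats pooled CV losses as independent pairs;
  samples augmented from the same source fish violate independence
  mildly — the grouped-fold mode exists to quantify that concern.
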