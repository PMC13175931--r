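---
title: "Neutrosophic similarity enhancement of OCT images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutrosophic similarity enhancement of OCT images: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octnss)
```

## The enhancement model

Optical coherence tomography renders the retina as stacked reflectivity
bands degraded by multiplicative speckle. The enhancement implemented
here treats every pixel as a *neutrosophic* element with three
memberships. With `I_N` the per-image min–max normalized intensity and
`G_d` the Sobel gradient magnitude of `I_N`:

* truth `T = I_N` — how bright, hence how likely to be reflective
  tissue;
* indeterminacy `I = 1 − (G_d − G_min)/(G_max − G_min + ε)` — pixels in
  flat neighborhoods are maximally ambiguous, strong edges are not;
* falsity `F = 1 − T`.

The per-pixel similarity to the ideal element `(T, I, F) = (1, 0, 0)` is
the cosine between the two membership vectors, which, because the ideal
is one-hot, collapses to

$$S = \frac{T}{\sqrt{T^2 + I^2 + F^2}}.$$

`S` is monotonically increasing in `T` at fixed `I` (a property the test
suite checks on a grid), so ordering of brightness is preserved while
ambiguous flat regions are pulled down. The map is quantized to 8 bits
(`round(255·S)`, half away from zero), locally equalized with CLAHE
(clip 2.0, 8×8 tiles), divided by 255 and mapped affinely back onto the
source range `[I_min, I_max]` recorded when the image was read
("defuzzification"). Consequences worth noting:

* the enhanced image can never leave the source intensity range;
* a constant image is a fixed point of the whole pipeline — its
  normalization is all zeros (the `ε` guard), gradients vanish,
  indeterminacy saturates at 1, and the degenerate defuzzification range
  collapses everything back to the input constant;
* the pipeline is a pure function of (pixels, parameters); no RNG
  anywhere.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `epsilon` | 1e-8 | intensity | guards both min–max denominators; a constant image yields `I = 1` everywhere rather than 0/0 |
| `alpha` | 255 | counts | 8-bit scale for the similarity map |
| `clahe_clip` | 2.0 | × mean bin count | histogram clip limit; effective integer limit is `max(1, floor(clip·tileArea/256))` |
| `clahe_tiles` | 8 × 8 | tiles | equalization tile grid |

The gradient normalization reuses the same `ε` guard as the intensity
normalization. The published recipe writes the guard only in the
normalization step; extending it to the gradient ratio is this package's
choice, since the algorithm must not divide by zero on flat images and
maximal indeterminacy is the natural flat-image limit.

## Numerical conventions

* **Rounding.** Every bracket quantization rounds half away from zero
  (127.5 → 128). `base::round()` rounds half to even and is not used on
  the 8-bit paths.
* **Sobel.** The printed kernels are applied as cross-correlation;
  convolution would only flip signs, which the magnitude discards.
  Borders use replicate (edge-clamp) padding so flat images produce
  exactly zero gradient and no spurious border edges appear.
* **CLAHE.** Per-tile 256-bin histograms are clipped at
  `max(1, floor(clip · tileArea / 256))`; the excess is redistributed in
  the classic two-phase scheme (uniform increment, then one count at a
  time over progressively offset scans), the cumulative histogram forms
  a continuous mapping onto `[0, 255]`, and pixels are bilinearly
  interpolated between the four surrounding tile-center mappings,
  clamped at the borders. Images whose dimensions do not divide the tile
  grid are padded by edge replication and cropped back. These
  conventions were chosen to agree with the widely deployed reference
  implementations; the test suite requires agreement within ±1 gray
  level of `EBImage::clahe` and bit-exactness against a straight-line
  loop transliteration. One subtlety: clipped equalization maps a
  *constant* tile to a constant, but not to its own value (the clipped,
  redistributed histogram integrates to a mid-scale plateau). The full
  pipeline still fixes constant images exactly because defuzzification
  collapses the degenerate range.
* **SSIM.** Wang et al. parameterization: 11×11 Gaussian window,
  σ = 1.5, `K1 = 0.01`, `K2 = 0.03`, data range 255, Gaussian-weighted
  population moments, averaged over the valid region only (no padding).
  Frozen fixtures pin the implementation to reference values computed
  with scikit-image's `structural_similarity`.
* **Entropy.** 256-bin Shannon entropy on 8-bit renderings of both
  images, `0·log 0 ≡ 0`; values therefore live in `[0, 8]` bits.

## The phantom generator

The generator emulates what the enhancement and harness need from real
OCT data, not the physics of interferometry. Each phantom is: seven
smooth curved reflectivity bands (alternating bright/dark, defaults
0.75/0.35/0.65/0.30/0.55/0.85/0.45) over a dark background; one of eight
parametric lesion archetypes painted on top (a broad bright RPE
elevation, a bright subretinal mass, a dark fluid dome, dark cystoid
pockets, bright scattered dots, small bright bumps, a foveal gap, or
nothing); multiplicative gamma speckle with shape 4 and mean 1 — a
standard first-order surrogate for fully developed OCT speckle; and a
contrast preset, where `"low"` compresses intensities into the middle
half of the 8-bit range (support 64..191), emulating a washed-out
acquisition.

Determinism is structural: the retina and speckle field depend only on
the seed, while lesion randomness draws from a separate hashed stream,
so two archetypes at the same seed differ only where their lesions
differ (tested for the macular hole). Dataset trees derive per-image
seeds from a stable hash of (seed, split, class, index): splits are
disjoint, trees are byte-reproducible, and the default 23/4/4 per class
is a 1:100 scale model of the public eight-class OCT collection's
2300/350/350 split.

What the phantoms do *not* model: realistic pathology morphology, axial
PSF and shadowing, vendor-specific noise statistics, or inter-patient
anatomical variability. Passing tests on phantoms therefore demonstrates
the correctness and the qualitative behavior of the pipeline (e.g. the
entropy-improvement direction on low-contrast inputs), not clinical
performance on real scans.

## The training harness

The harness encodes the two-stage fine-tuning schedule as data
(`build_plan()`): batch 32, categorical cross-entropy, stage 1 frozen
backbone at Adam lr 1e-3 for 10 epochs, stage 2 with the last 50 layers
unfrozen at 1e-4 for 20 epochs, dropout 0.5, augmentation (rotation ≤15°,
zoom ≤10%, translation ≤10%, brightness ±10%, horizontal flip — the
transform families are prescribed, the magnitudes are package defaults),
early stopping with best-weight restoration (patience 5, an assumption —
no published value exists) and plateau LR reduction to 1e-6. Grayscale
inputs are replicated to three channels to fit the declared
`224×224×3` input; the input size is overridable because desk-scale
runs use 32×32.

Design choices that deserve justification:

* **Backbone.** No deep-learning framework ships with the package's
  environment, so the desk-scale backbone is a three-block CNN
  (conv–batchnorm–ReLU with 8/16/32 filters, average pooling, global
  average pooling) written in plain R with analytically derived
  gradients (numerically checked in the tests). The backbone object is a
  contract — ordered layers, pooled feature output, freeze-all /
  unfreeze-last-N — so a wrapper around any large pretrained network
  can be substituted without touching the harness.
* **Zero-initialized head.** The softmax head starts at zero weights:
  from uniform logits every optimizer step moves along the class signal
  instead of fighting random-projection noise. At full scale this is a
  common fine-tuning convention; at desk scale (a dozen optimizer steps
  per stage) it is the difference between learning and noise.
* **Batch normalization + precise-BN calibration.** Pooled features of
  a random, frozen CNN are small and dominated by one shared
  "brightness" direction; a linear head cannot become discriminative in
  few steps on such features. Batch normalization restores per-feature
  scale and centering. Because only a few dozen batches ever flow
  through the network, the exponential running statistics used at
  inference would lag badly, so after training the harness recomputes
  them exactly (cumulative averages over the clean training inputs with
  final weights) — the "precise BN" procedure. Frozen BN layers still
  update batch statistics during stage-1 forward passes; their γ/β do
  not train.
* **Augmentation and shuffling** draw from per-epoch seeds hashed from
  the plan seed, so a fixed seed reproduces the entire pixel stream and
  the training history bit for bit.
* **Enhancement plumbing.** `prepare_batches(..., enhance = TRUE)` runs
  the deterministic enhancement in memory per image; the test suite
  checks it equals enhancing each image first and then streaming. For
  large datasets, `batch_enhance()` caches 8-bit enhanced renderings on
  disk instead.

## Problem sizes

The shipped tests and the acceptance script run everything at desk
scale, chosen so a full pass stays comfortable on one CPU: 224×224
phantoms for the enhancement properties (50–100 images per property),
64×64 rasters for the oracle equivalences, and the 23/4/4-per-class
dataset with 32×32 network inputs and 2+2 epochs over three seeds for
the training smoke run. At these sizes the smoke run reaches roughly
25–35% test accuracy — far above the 12.5% chance level of the
eight-class problem, which is all the smoke test claims. Full-scale
training (a pretrained backbone, the real dataset, 10+20 epochs) is out
of scope here; the harness exposes the hooks for it but the package
makes no claims about real-data accuracy.

## Known limitations

* The similarity score uses the single intensity criterion; no
  multi-criteria weighting, neutrosophic entropy, or α-mean/γ-median
  operators.
* CLAHE conventions vary across libraries (clip semantics, LUT scaling,
  interpolation); agreement is guaranteed only within ±1 gray level of
  the reference family implemented here.
* `quality_report()` renders 16-bit inputs down to 8 bits for the
  histogram metrics, which discards fine intensity resolution.
* The pure-R network trains small models only; it has no GPU path, no
  convolution striding, and its runtime grows linearly in pixels ×
  filters.
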