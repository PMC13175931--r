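# octnss

Neutrosophic similarity score (NSS) enhancement for retinal optical
coherence tomography (OCT) images, with the surrounding tooling needed to
study it: image quality metrics, a seeded layered-retina phantom
generator, and a two-stage transfer-learning harness.

## The problem and the method

OCT B-scans are corrupted by multiplicative speckle and often show weak
local contrast, which obscures the layered retinal anatomy that both
clinicians and downstream classifiers depend on. `octnss` enhances a
grayscale OCT image `I(x, y)` by reasoning about each pixel in the
*neutrosophic domain*, where it carries three memberships:

- **truth** `T = I_N`, the min–max normalized intensity
  `I_N = (I − I_min) / (I_max − I_min + ε)`;
- **indeterminacy** `I = 1 − (G_d − G_min) / (G_max − G_min + ε)`, one
  minus the normalized Sobel gradient magnitude
  `G_d = sqrt(G_x² + G_y²)` — flat, ambiguous regions are maximally
  indeterminate;
- **falsity** `F = 1 − T`.

Each pixel's triple is scored by its cosine similarity to the *ideal
alternative* `A* = (1, 0, 0)` (a perfectly bright, unambiguous pixel):

```
S = T / sqrt(T² + I² + F²)
```

High `S` marks confident bright structure; low `S` marks dark or
ambiguous regions. The score map is scaled to 8 bits, passed through
contrast-limited adaptive histogram equalization (CLAHE, clip limit 2.0,
8×8 tiles), renormalized, and *defuzzified* back onto the source range:
`Ĩ = E_norm · (I_max − I_min) + I_min`. The result preserves the
original intensity range while boosting local contrast of structurally
meaningful regions.

Quality is assessed with PSNR, SSIM (Wang et al. parameterization),
256-bin Shannon entropy, and the relative entropy improvement
`100 · (H_enh − H_orig) / H_orig`.

The classification harness encodes a two-stage fine-tuning schedule for
an image classifier fed with enhanced scans: stage 1 trains a
dropout(0.5) + softmax head on a frozen backbone (Adam, lr 1e-3, batch
32, 10 epochs), stage 2 unfreezes the last 50 backbone layers at lr 1e-4
for 20 epochs, with augmentation, early stopping (best-weight restore)
and plateau learning-rate reduction to 1e-6. The backbone is pluggable; a
small pure-R convolutional backbone (`backbone_tinycnn()`) ships for
desk-scale experiments, and every schedule constant can be overridden
through `build_plan()`.

Because the public OCT datasets are large external downloads, the package
includes a deterministic phantom generator: curved retinal reflectivity
bands, mean-1 gamma speckle, and eight parametric lesion archetypes
(AMD elevation, CNV mass, CSR fluid dome, DME cysts, DR dots, drusen
bumps, macular hole, normal) emitted as class-folder datasets that every
other module can consume.

## Worked example

```r
library(octnss)

ph  <- generate_phantom(phantom_spec(lesion_archetype = "CSR_fluid_dome",
                                     contrast_preset = "low", seed = 3))
res <- enhance_image(ph)
range(res$enhanced$pixels)
#> [1]  64.49804 191.00000
quality_report(ph, res$enhanced)
#>   psnr_db      ssim entropy_orig entropy_enh entropy_improvement_pct
#> 1  31.937 0.9709864      5.62796    5.865918                4.228147
```

The phantom is a washed-out (low-contrast preset, support 64..191)
B-scan with a subretinal fluid dome. Enhancement keeps the output inside
the recorded range (the defuzzification contract), and the entropy of the
8-bit rendering rises by 4.2% — the enhanced image carries more textural
information — while SSIM 0.97 confirms the anatomy was not distorted.

Training at desk scale:

```r
ds   <- generate_dataset(phantom_dataset_spec(root = "phantoms", seed = 7))
plan <- build_plan(list(input_size = c(32, 32, 3),
                        stage1 = list(epochs = 2), stage2 = list(epochs = 2)))
bb   <- backbone_tinycnn(c(32L, 32L))
m    <- train_model(plan, bb,
                    prepare_batches(ds$train, plan, training = TRUE),
                    prepare_batches(ds$val, plan))
evaluate_model(m, prepare_batches(ds$test, plan))$accuracy
#> [1] 0.3125
```

A command-line front end (`inst/cli/octnss`) wraps the same functions:
`enhance`, `batch-enhance`, `metrics`, `phantom`, `train`, `evaluate`.

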