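# Synthetic layered-retina OCT phantoms: curved reflectivity bands,
# multiplicative gamma speckle and eight parametric lesion archetypes.

#' Lesion archetypes covered by the phantom generator
#'
#' Eight parametric geometries standing in for the retinal disease
#' categories of OCT classification datasets: broad RPE elevation (AMD),
#' bright subretinal mass (CNV), hyporeflective fluid dome (CSR), cystoid
#' pockets (DME), scattered hyperreflective dots (DR), small RPE bumps
#' (drusen), a foveal gap (macular hole) and an unperturbed retina
#' (normal).
#'
#' @format Character vector of length 8.
#' @export
PHANTOM_CLASSES <- c("AMD_elevation", "CNV_subretinal_mass", "CSR_fluid_dome",
                     "DME_cystoid_pockets", "DR_hyperreflective_dots",
                     "DRUSEN_bumps", "MH_foveal_gap", "NORMAL")

#' Specification of a single OCT phantom
#'
#' @param height,width Image size in pixels, at least 32. Default 224,
#'   the input size of the classification harness.
#' @param n_layers Number of retinal reflectivity bands. Default 7.
#' @param layer_intensities Band reflectivities in `[0, 1]`, one per
#'   layer, superficial to deep. Defaults to an alternating bright/dark
#'   profile reminiscent of real B-scans.
#' @param lesion_archetype One of [PHANTOM_CLASSES].
#' @param speckle_shape Shape of the mean-1 multiplicative gamma speckle
#'   (larger = less noisy). Default 4, a standard first-order surrogate
#'   for fully developed OCT speckle.
#' @param contrast_preset `"normal"` uses the full 8-bit range; `"low"`
#'   compresses intensities into the middle half (`64..191`), emulating a
#'   washed-out acquisition.
#' @param seed Integer seed; the phantom is fully determined by it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 224L, width = 224L, n_layers = 7L,
                         layer_intensities = NULL,
                         lesion_archetype = "NORMAL",
                         speckle_shape = 4.0,
                         contrast_preset = c("normal", "low"),
                         seed = 1L) {
  contrast_preset <- match.arg(contrast_preset)
  if (height < 32L || width < 32L)
    stop("phantoms must be at least 32 x 32")
  if (!lesion_archetype %in% PHANTOM_CLASSES)
    stop("unknown lesion archetype: ", lesion_archetype)
  if (is.null(layer_intensities))
    layer_intensities <- rep_len(c(0.75, 0.35, 0.65, 0.30, 0.55, 0.85, 0.45),
                                 n_layers)
  if (length(layer_intensities) != n_layers)
    stop("layer_intensities must have length n_layers")
  if (any(layer_intensities < 0 | layer_intensities > 1))
    stop("layer_intensities must lie in [0, 1]")
  if (speckle_shape <= 0) stop("speckle_shape must be positive")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_layers = as.integer(n_layers),
                 layer_intensities = layer_intensities,
                 lesion_archetype = lesion_archetype,
                 speckle_shape = speckle_shape,
                 contrast_preset = contrast_preset,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a layered-retina OCT phantom
#'
#' Renders smooth curved reflectivity bands on a dark background, applies
#' the archetype's geometric perturbation, multiplies by mean-1 gamma
#' speckle and maps through the contrast preset. The base retina and the
#' speckle field depend only on `seed` (not on the archetype), so two
#' archetypes generated at the same seed differ only where their lesions
#' differ. Output pixels are 8-bit integers.
#'
#' @param spec A [phantom_spec()].
#' @return A [gray_image()] with values in `0..255`.
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 64, width = 64,
#'                                     lesion_archetype = "CSR_fluid_dome"))
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  H <- spec$height; W <- spec$width
  base <- NULL; spk <- NULL; geom <- NULL
  with_seed(spec$seed, {
    x <- seq_len(W)
    top_frac <- runif(1, 0.22, 0.32)
    amp <- runif(1, 0.02, 0.05)
    ph <- runif(1, 0, 2 * pi)
    curv <- runif(1, 0.02, 0.08)
    thick <- runif(1, 0.40, 0.48) * H
    ytop <- H * (top_frac + amp * sin(2 * pi * x / W + ph) +
                   curv * ((x - W / 2) / (W / 2))^2)
    # band boundaries: evenly spaced fractions with gentle per-boundary waves
    nb <- spec$n_layers + 1L
    fr <- seq(0, 1, length.out = nb)
    wamp <- runif(nb, 0, 0.012)
    wph <- runif(nb, 0, 2 * pi)
    bnd <- matrix(0, nb, W)
    for (l in seq_len(nb))
      bnd[l, ] <- ytop + thick * (fr[l] + wamp[l] * sin(2 * pi * x / W + wph[l]))
    base <- matrix(0.05, H, W)
    Y <- matrix(seq_len(H), H, W)
    for (l in seq_len(spec$n_layers)) {
      lo <- matrix(bnd[l, ], H, W, byrow = TRUE)
      hi <- matrix(bnd[l + 1L, ], H, W, byrow = TRUE)
      base[Y >= lo & Y < hi] <- spec$layer_intensities[l]
    }
    spk <- matrix(draw_speckle(H * W, spec$speckle_shape), H, W)
    geom <- list(ytop = ytop, ybot = bnd[nb, ], thick = thick, Y = Y)
  })
  base <- with_seed(stable_hash(spec$seed, spec$lesion_archetype, "lesion"),
                    apply_archetype(base, spec$lesion_archetype, geom, H, W))
  img01 <- clamp01(base * spk)
  if (spec$contrast_preset == "low") img01 <- 0.25 + 0.5 * img01
  px <- clamp(round_half_away(img01 * 255), 0, 255)
  gray_image(px, bit_depth = 8L)
}

# Mean-1 multiplicative gamma speckle: shape k, rate k, so E[s] = 1 and
# Var[s] = 1/k. Shape 4 is the generator default.
draw_speckle <- function(n, shape) rgamma(n, shape = shape, rate = shape)

# Paint the archetype's lesion onto the base reflectivity image. All
# randomness here comes from a lesion-specific stream, so the underlying
# retina and speckle are shared across archetypes at equal seeds.
apply_archetype <- function(base, archetype, geom, H, W) {
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  Y <- geom$Y
  ytopM <- matrix(geom$ytop, H, W, byrow = TRUE)
  ybotM <- matrix(geom$ybot, H, W, byrow = TRUE)
  th <- geom$thick
  cx <- W / 2
  ellipse <- function(x0, y0, a, b) ((X - x0) / a)^2 + ((Y - y0) / b)^2 <= 1
  switch(archetype,
    NORMAL = base,
    MH_foveal_gap = {
      halfw <- 0.09 * W
      depth <- 0.55 * (1 - ((X - cx) / halfw)^2)
      mask <- abs(X - cx) < halfw & Y >= ytopM & Y < ytopM + depth * th
      base[mask] <- 0.05
      base
    },
    CSR_fluid_dome = {
      x0 <- cx + runif(1, -0.08, 0.08) * W
      base[ellipse(x0, ytopM + 0.72 * th, 0.22 * W, 0.26 * th)] <- 0.08
      base
    },
    DME_cystoid_pockets = {
      n <- 5L
      xs <- runif(n, 0.15 * W, 0.85 * W)
      ds <- runif(n, 0.35, 0.75)
      for (k in seq_len(n))
        base[ellipse(xs[k], ytopM + ds[k] * th, 0.045 * W, 0.09 * th)] <- 0.10
      base
    },
    DR_hyperreflective_dots = {
      n <- 25L
      xs <- runif(n, 0.05 * W, 0.95 * W)
      ds <- runif(n, 0.15, 0.9)
      rs <- runif(n, 1.2, 2.5)
      for (k in seq_len(n))
        base[ellipse(xs[k], ytopM + ds[k] * th, rs[k], rs[k])] <- 0.95
      base
    },
    CNV_subretinal_mass = {
      x0 <- cx + runif(1, -0.1, 0.1) * W
      base[ellipse(x0, ybotM - 0.04 * th, 0.16 * W, 0.14 * th)] <- 0.92
      base
    },
    AMD_elevation = {
      x0 <- cx + runif(1, -0.1, 0.1) * W
      halfw <- 0.20 * W
      hb <- 0.28 * (1 - ((X - x0) / halfw)^2)
      mask <- abs(X - x0) < halfw & Y >= ybotM - hb * th & Y < ybotM
      base[mask] <- 0.88
      base
    },
    DRUSEN_bumps = {
      n <- 6L
      xs <- runif(n, 0.1 * W, 0.9 * W)
      for (k in seq_len(n)) {
        halfw <- runif(1, 0.025, 0.04) * W
        hb <- runif(1, 0.08, 0.14) * (1 - ((X - xs[k]) / halfw)^2)
        mask <- abs(X - xs[k]) < halfw & Y >= ybotM - hb * th & Y < ybotM
        base[mask] <- 0.85
      }
      base
    },
    stop("unknown lesion archetype: ", archetype))
}

#' Specification of a phantom class-folder dataset
#'
#' @param root Directory the dataset is written under.
#' @param n_train,n_val,n_test Images per class and split. Defaults
#'   23/4/4, a 1:100 scale model of the 2300/350/350 per-class splits of
#'   the public retinal OCT (C8) dataset.
#' @param height,width Phantom size, default 224.
#' @param contrast_preset,speckle_shape Passed to every [phantom_spec()].
#' @param seed Master seed; per-image seeds are derived from a stable
#'   hash of `(seed, split, class, index)` so splits draw disjoint,
#'   reproducible streams.
#' @return An object of class `phantom_dataset_spec`.
#' @export
phantom_dataset_spec <- function(root, n_train = 23L, n_val = 4L, n_test = 4L,
                                 height = 224L, width = 224L,
                                 contrast_preset = c("normal", "low"),
                                 speckle_shape = 4.0, seed = 1L) {
  contrast_preset <- match.arg(contrast_preset)
  counts <- c(train = as.integer(n_train), val = as.integer(n_val),
              test = as.integer(n_test))
  if (any(counts < 1L)) stop("all per-class counts must be >= 1")
  structure(list(root = root, counts = counts,
                 height = as.integer(height), width = as.integer(width),
                 contrast_preset = contrast_preset,
                 speckle_shape = speckle_shape, seed = as.integer(seed)),
            class = "phantom_dataset_spec")
}

#' Generate a phantom class-folder dataset on disk
#'
#' Writes `<root>/<split>/<CLASS>/phantom_<k>.png` for all eight
#' archetypes and the three splits, then indexes each split. Two runs at
#' the same seed produce byte-identical trees.
#'
#' @param spec A [phantom_dataset_spec()].
#' @return A named list of [index_dataset()] results for `train`, `val`
#'   and `test`.
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "phantom_dataset_spec"))
    stop("spec must be a phantom_dataset_spec")
  classes <- sort(PHANTOM_CLASSES, method = "radix")
  for (split in names(spec$counts)) {
    for (cl in classes) {
      dir <- file.path(spec$root, split, cl)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_len(spec$counts[[split]])) {
        s <- stable_hash(spec$seed, split, cl, k)
        ph <- generate_phantom(phantom_spec(
          height = spec$height, width = spec$width,
          lesion_archetype = cl, speckle_shape = spec$speckle_shape,
          contrast_preset = spec$contrast_preset, seed = s))
        write_gray(ph, file.path(dir, sprintf("phantom_%04d.png", k)))
      }
    }
  }
  lapply(stats::setNames(nm = names(spec$counts)),
         function(split) index_dataset(spec$root, split))
}
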