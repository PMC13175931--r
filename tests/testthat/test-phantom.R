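test_that("phantom_spec validates its fields", {
  expect_error(phantom_spec(height = 16), "32 x 32")
  expect_error(phantom_spec(lesion_archetype = "GLAUCOMA"), "unknown")
  expect_error(phantom_spec(layer_intensities = c(0.5, 0.5)), "n_layers")
  expect_error(phantom_spec(layer_intensities = rep(2, 7)), "\\[0, 1\\]")
  expect_error(phantom_spec(speckle_shape = 0), "positive")
})

test_that("phantoms are a deterministic function of their spec", {
  sp <- phantom_spec(height = 64, width = 64,
                     lesion_archetype = "CNV_subretinal_mass", seed = 5)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$pixels, p2$pixels)
  expect_identical(p1$bit_depth, 8L)
  expect_true(all(p1$pixels >= 0 & p1$pixels <= 255))
  # a different seed gives a different image
  p3 <- generate_phantom(phantom_spec(height = 64, width = 64,
                                      lesion_archetype = "CNV_subretinal_mass",
                                      seed = 6))
  expect_false(identical(p1$pixels, p3$pixels))
  # the generator leaves the caller's RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(generate_phantom(sp))
  expect_identical(.Random.seed, before)
})

test_that("lesions are local: a macular hole only edits the foveal gap", {
  for (seed in c(3, 14)) {
    nrm <- generate_phantom(phantom_spec(lesion_archetype = "NORMAL",
                                         seed = seed))
    mh <- generate_phantom(phantom_spec(lesion_archetype = "MH_foveal_gap",
                                        seed = seed))
    diffcols <- which(colSums(nrm$pixels != mh$pixels) > 0)
    expect_gt(length(diffcols), 0)
    # the gap is a band of width 2 * 0.09 * W around the image center
    W <- 224
    expect_true(all(abs(diffcols - W / 2) < 0.09 * W + 1))
  }
})

test_that("the low-contrast preset confines the histogram to [64, 191]", {
  for (cl in c("NORMAL", "DME_cystoid_pockets")) {
    p <- generate_phantom(phantom_spec(height = 64, width = 64,
                                       lesion_archetype = cl,
                                       contrast_preset = "low", seed = 2))
    expect_gte(min(p$pixels), 64)
    expect_lte(max(p$pixels), 191)
  }
})

test_that("multiplicative speckle has empirical mean 1", {
  set.seed(1001)
  s <- octnss:::draw_speckle(1e5, 4)
  expect_lt(abs(mean(s) - 1), 0.05)
  expect_true(all(s > 0))
})

test_that("generated datasets have exact counts and reproducible bytes", {
  ds <- fixture_phantom_dataset()
  expect_equal(nrow(ds$train$entries), 184L)
  expect_equal(nrow(ds$val$entries), 32L)
  expect_equal(nrow(ds$test$entries), 32L)
  expect_equal(length(ds$train$class_names), 8L)
  expect_equal(unname(ds$train$counts), rep(23L, 8))

  # regenerating one file at the same master seed is byte-identical,
  # and distinct splits draw from disjoint seed streams
  root2 <- file.path(tempdir(), "octnss_ds_rep")
  unlink(root2, recursive = TRUE)
  generate_dataset(phantom_dataset_spec(root = root2, n_train = 1,
                                        n_val = 1, n_test = 1, seed = 7L))
  f_new <- file.path(root2, "train", "NORMAL", "phantom_0001.png")
  f_old <- file.path(dirname(ds$train$entries$path[1]), "..", "NORMAL",
                     "phantom_0001.png")
  expect_identical(readBin(f_new, "raw", file.size(f_new)),
                   readBin(normalizePath(f_old), "raw", file.size(f_old)))
  tr1 <- read_gray(file.path(root2, "train", "NORMAL", "phantom_0001.png"))
  te1 <- read_gray(file.path(root2, "test", "NORMAL", "phantom_0001.png"))
  expect_false(identical(tr1$pixels, te1$pixels))
})

test_that("archetypes separate under a nearest-class-mean pixel classifier", {
  classes <- PHANTOM_CLASSES
  down <- function(img) as.vector(octnss:::warp_bilinear(img$pixels, 16, 16))
  n_per <- 50L
  feats <- list(); labs <- character(0)
  for (cl in classes) {
    for (k in seq_len(n_per)) {
      p <- generate_phantom(phantom_spec(height = 96, width = 96,
                                         lesion_archetype = cl,
                                         seed = octnss:::stable_hash("sep", cl, k)))
      feats[[length(feats) + 1L]] <- down(p)
      labs <- c(labs, cl)
    }
  }
  X <- do.call(rbind, feats)
  train <- rep(rep(c(TRUE, FALSE), each = n_per / 2), times = length(classes))
  mu <- sapply(classes, function(cl)
    colMeans(X[train & labs == cl, , drop = FALSE]))
  pred <- classes[apply(X[!train, ], 1, function(f)
    which.min(colSums((mu - f)^2)))]
  acc <- mean(pred == labs[!train])
  expect_gt(acc, 1 / 8)
})
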