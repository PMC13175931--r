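test_that("the default plan encodes the two-stage schedule", {
  plan <- build_plan()
  expect_equal(plan$input_size, c(224L, 224L, 3L))
  expect_equal(plan$n_classes, 8L)
  expect_equal(plan$batch_size, 32L)
  expect_equal(plan$loss, "categorical_crossentropy")
  expect_true(plan$stage1$frozen_base)
  expect_equal(plan$stage1$lr, 1e-3)
  expect_equal(plan$stage1$epochs, 10L)
  expect_equal(plan$stage2$lr, 1e-4)
  expect_equal(plan$stage2$epochs, 20L)
  expect_equal(plan$stage2$unfreeze_last_n_layers, 50L)
  expect_equal(plan$dropout, 0.5)
  expect_true(plan$callbacks$early_stopping_restore_best)
  expect_equal(plan$callbacks$reduce_lr_min, 1e-6)
})

test_that("plan overrides merge, log, and are validated", {
  expect_message(plan <- build_plan(list(stage1 = list(epochs = 2L),
                                         stage2 = list(epochs = 2L))),
                 "overrides")
  expect_equal(plan$stage1$epochs, 2L)
  expect_equal(plan$stage2$epochs, 2L)
  expect_equal(plan$batch_size, 32L)     # untouched fields keep defaults
  expect_equal(plan$stage2$unfreeze_last_n_layers, 50L)
  expect_error(build_plan(list(stage2 = list(lr = 1e-2))), "below stage 1")
  expect_error(build_plan(list(nonsense = 1)), "unknown plan fields")
  expect_error(build_plan(list(callbacks = list(reduce_lr_min = 1e-3))),
               "minimum learning rate")
  expect_error(build_plan(list(stage1 = list(epochs = 0L))), "epochs")
  # config can come from a YAML file
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("batch_size: 16\nseed: 3", f)
  plan2 <- suppressMessages(build_plan(f))
  expect_equal(plan2$batch_size, 16L)
  expect_equal(plan2$seed, 3L)
})

test_that("early stopping and plateau reduction follow their contracts", {
  ns <- asNamespace("octnss")
  st <- ns$es_init(patience = 1L, lr = 1e-3, factor = 0.5,
                   lr_patience = 2L, min_lr = 1e-6)
  st <- ns$es_update(st, 1.0, 1L)   # improvement
  expect_equal(st$best_epoch, 1L)
  expect_false(st$stop)
  st <- ns$es_update(st, 1.2, 2L)   # val loss rises: patience 1 exhausted
  expect_true(st$stop)
  expect_equal(st$best_epoch, 1L)
  # plateau reduction bottoms out at min_lr
  st2 <- ns$es_init(patience = 10L, lr = 4e-6, factor = 0.5,
                    lr_patience = 1L, min_lr = 1e-6)
  st2 <- ns$es_update(st2, 1.0, 1L)
  for (e in 2:6) st2 <- ns$es_update(st2, 1.0 + e / 10, e)
  expect_equal(st2$lr, 1e-6)
})

test_that("layer gradients agree with numerical differentiation", {
  ns <- asNamespace("octnss")
  set.seed(42)
  x <- array(rnorm(2 * 8 * 8 * 3), c(2, 8, 8, 3))
  y <- diag(8)[c(2, 6), ]
  bb <- ns$with_seed(3, backbone_tinycnn(c(8L, 8L)))
  hd <- ns$layer_dense(32L, 8L)
  layers <- c(bb$layers, list(hd))
  fwd_loss <- function() {
    o <- x
    for (l in layers) o <- ns$forward_layer(l, o, training = l$type == "batchnorm")
    ns$softmax_ce(o, y)$loss
  }
  o <- x
  for (l in layers) o <- ns$forward_layer(l, o, training = l$type == "batchnorm")
  sc <- ns$softmax_ce(o, y)
  dy <- sc$dlogits
  for (li in rev(seq_along(layers)))
    dy <- ns$backward_layer(layers[[li]], dy, want_dx = li > 1)
  for (pick in list(layers[[1]], layers[[2]], layers[[5]], hd)) {
    W0 <- pick$W
    idx <- sample(length(W0), min(6, length(W0)))
    for (i in idx) {
      Wp <- W0; Wp[i] <- W0[i] + 1e-6; pick$W <- Wp; f1 <- fwd_loss()
      Wm <- W0; Wm[i] <- W0[i] - 1e-6; pick$W <- Wm; f2 <- fwd_loss()
      pick$W <- W0
      expect_equal(pick$gW[i], (f1 - f2) / 2e-6, tolerance = 1e-4)
    }
  }
})

test_that("streams resize, one-hot encode and batch with ceiling division", {
  ds <- fixture_phantom_dataset()
  plan <- suppressMessages(build_plan(list(input_size = c(32L, 32L, 3L))))
  tr <- prepare_batches(ds$train, plan, training = TRUE)
  expect_equal(dim(tr$x), c(184L, 32L, 32L, 3L))
  expect_true(all(tr$x >= 0 & tr$x <= 1))
  expect_equal(rowSums(tr$y), rep(1, 184))
  expect_equal(colSums(tr$y), rep(23, 8))
  b <- tr$epoch_batches(1)
  expect_length(b, 6L)            # ceiling(184 / 32)
  expect_equal(dim(b[[6]]$x)[1], 184L - 5L * 32L)
  # the three channels replicate the grayscale plane
  expect_equal(tr$x[1, , , 1], tr$x[1, , , 3])
  # class-count mismatch with the plan is refused
  root <- fixture_mini_tree()
  idx2 <- suppressWarnings(index_dataset(root, "train"))
  expect_error(prepare_batches(idx2, plan), "classes")
})

test_that("training streams re-augment deterministically; eval streams are fixed", {
  ds <- fixture_phantom_dataset()
  plan <- suppressMessages(build_plan(list(input_size = c(32L, 32L, 3L),
                                           seed = 99L)))
  small <- ds$val
  tr1 <- prepare_batches(small, plan, training = TRUE)
  tr2 <- prepare_batches(small, plan, training = TRUE)
  b1 <- tr1$epoch_batches(1); b2 <- tr2$epoch_batches(1)
  expect_identical(b1[[1]]$x, b2[[1]]$x)
  expect_identical(b1[[1]]$y, b2[[1]]$y)
  # different epochs draw different augmentations
  b1e2 <- tr1$epoch_batches(2)
  expect_false(identical(b1[[1]]$x, b1e2[[1]]$x))
  # validation streams: no augmentation, stable across calls
  va <- prepare_batches(small, plan)
  expect_identical(va$epoch_batches(1)[[1]]$x, va$epoch_batches(5)[[1]]$x)
  expect_identical(va$epoch_batches(1)[[1]]$x,
                   va$x[1:min(32, va$n), , , , drop = FALSE])
})

test_that("on-the-fly enhancement equals per-image enhancement", {
  ds <- fixture_phantom_dataset()
  plan <- suppressMessages(build_plan(list(input_size = c(32L, 32L, 3L))))
  for (i in c(1L, 30L)) {
    img <- read_gray(ds$val$entries$path[i])
    via_flag <- image_to_input(img, plan, enhance = TRUE)
    via_fn <- image_to_input(enhance_image(img)$enhanced, plan,
                             enhance = FALSE)
    expect_equal(via_flag, via_fn, tolerance = 1e-12)
  }
})

test_that("stage 1 leaves frozen backbone weights bit-identical", {
  ds <- fixture_phantom_dataset()
  plan <- suppressMessages(build_plan(list(
    input_size = c(32L, 32L, 3L), seed = 5L,
    stage1 = list(epochs = 1L),
    stage2 = list(epochs = 1L, unfreeze_last_n_layers = 0L),
    callbacks = list(early_stopping_patience = 10L,
                     early_stopping_restore_best = FALSE))))
  tr <- prepare_batches(ds$val, plan, training = TRUE)
  bb <- octnss:::with_seed(5, backbone_tinycnn(c(32L, 32L)))
  w_before <- lapply(bb$layers, function(l) l$W)
  m <- train_model(plan, bb, tr, NULL)
  w_after <- lapply(bb$layers, function(l) l$W)
  expect_identical(w_before, w_after)   # nothing unfrozen in either stage
  # the head did train
  expect_false(all(m$head[[2]]$W == 0))
})

test_that("training histories are reproducible at a fixed seed", {
  ds <- fixture_phantom_dataset()
  plan <- suppressMessages(build_plan(list(
    input_size = c(16L, 16L, 3L), seed = 8L,
    stage1 = list(epochs = 2L), stage2 = list(epochs = 2L),
    callbacks = list(early_stopping_patience = 10L))))
  va <- prepare_batches(ds$val, plan)
  run <- function() {
    tr <- prepare_batches(ds$val, plan, training = TRUE)
    bb <- octnss:::with_seed(8, backbone_tinycnn(c(16L, 16L)))
    train_model(plan, bb, tr, va)
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 4L)
  expect_identical(colnames(m1$history),
                   c("stage", "epoch", "lr", "train_loss", "train_acc",
                     "val_loss", "val_acc"))
  # evaluation produces a coherent report on the test stream
  te <- prepare_batches(ds$test, plan)
  rep <- evaluate_model(m1, te)
  expect_s3_class(rep, "classification_report")
  expect_equal(unname(rowSums(rep$confusion)), rep$per_class$support)
  expect_equal(sum(rep$per_class$support), 32L)
})
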