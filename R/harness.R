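# Two-stage transfer-learning harness: training plan, batch preparation
# with optional enhancement and seeded augmentation, the two-stage
# training loop with early stopping and learning-rate reduction, and test
# evaluation.

#' Build a two-stage training plan
#'
#' The defaults encode the full-scale schedule: 224 x 224 x 3 inputs, 8
#' classes, batch size 32, categorical cross-entropy, stage 1 with the
#' backbone frozen (Adam, lr 1e-3, 10 epochs), stage 2 with the last 50
#' layers unfrozen (Adam, lr 1e-4, 20 epochs), dropout 0.5,
#' rotation/zoom/translation/brightness/flip augmentation, early stopping
#' with best-weight restoration and plateau learning-rate reduction down
#' to 1e-6. Every field can be overridden for desk-scale runs; overrides
#' are logged via `message()`.
#'
#' @param config `NULL`, a named list of overrides, or the path of a
#'   YAML/JSON file containing one.
#' @return An object of class `train_plan`.
#' @examples
#' plan <- build_plan(list(input_size = c(32, 32, 3),
#'                         stage1 = list(epochs = 2),
#'                         stage2 = list(epochs = 2)))
#' @export
build_plan <- function(config = NULL) {
  defaults <- list(
    input_size = c(224L, 224L, 3L),
    n_classes = 8L,
    batch_size = 32L,
    loss = "categorical_crossentropy",
    stage1 = list(frozen_base = TRUE, optimizer = "adam",
                  lr = 1e-3, epochs = 10L),
    stage2 = list(unfreeze_last_n_layers = 50L, optimizer = "adam",
                  lr = 1e-4, epochs = 20L),
    dropout = 0.5,
    augmentation = list(rotation_deg = 15, zoom = 0.10, translation = 0.10,
                        brightness = 0.10, horizontal_flip = TRUE),
    callbacks = list(early_stopping_patience = 5L,
                     early_stopping_restore_best = TRUE,
                     reduce_lr_factor = 0.5, reduce_lr_patience = 2L,
                     reduce_lr_min = 1e-6),
    seed = 42L)
  if (is.character(config)) {
    config <- if (tolower(tools::file_ext(config)) == "json")
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  plan <- defaults
  if (!is.null(config)) {
    if (!is.list(config)) stop("config must be NULL, a list or a file path")
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown) > 0L)
      stop("unknown plan fields: ", paste(unknown, collapse = ", "))
    plan <- utils::modifyList(defaults, config)
    message("plan overrides: ", paste(names(config), collapse = ", "))
  }
  if (length(plan$input_size) == 2L) plan$input_size <- c(plan$input_size, 3L)
  if (length(plan$input_size) != 3L)
    stop("input_size must be (height, width, channels)")
  if (plan$stage2$lr >= plan$stage1$lr)
    stop("stage 2 learning rate must be below stage 1 (fine-tuning)")
  if (plan$stage1$epochs < 1L || plan$stage2$epochs < 1L)
    stop("epochs must be >= 1")
  if (plan$callbacks$reduce_lr_min > plan$stage2$lr)
    stop("minimum learning rate must not exceed the stage 2 rate")
  if (plan$batch_size < 1L) stop("batch_size must be >= 1")
  if (plan$dropout < 0 || plan$dropout >= 1)
    stop("dropout must lie in [0, 1)")
  structure(plan, class = "train_plan")
}

# Bilinear sampling of `m` on an output grid that is rotated by `angle`
# degrees, scaled by `zoom` about the image center and shifted by
# (tx, ty) pixels; source coordinates are clamped to the image (edge
# extension). With the identity transform and differing output dims this
# is plain bilinear resizing.
warp_bilinear <- function(m, h_out, w_out, angle = 0, zoom = 1,
                          tx = 0, ty = 0) {
  H <- nrow(m); W <- ncol(m)
  oy <- (seq_len(h_out) - 0.5) * H / h_out
  ox <- (seq_len(w_out) - 0.5) * W / w_out
  cy <- H / 2; cx <- W / 2
  YY <- matrix(oy - cy, h_out, w_out)
  XX <- matrix(ox - cx, h_out, w_out, byrow = TRUE)
  th <- angle * pi / 180
  sy <- (cos(th) * YY - sin(th) * XX) / zoom + cy - ty
  sx <- (sin(th) * YY + cos(th) * XX) / zoom + cx - tx
  sy <- clamp(sy - 0.5, 0, H - 1)
  sx <- clamp(sx - 0.5, 0, W - 1)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  g <- function(yi, xi) m[cbind(as.vector(yi) + 1L, as.vector(xi) + 1L)]
  v <- (1 - fy) * ((1 - fx) * g(y0, x0) + fx * g(y0, x1)) +
    fy * ((1 - fx) * g(y1, x0) + fx * g(y1, x1))
  matrix(v, h_out, w_out)
}

#' Convert one image to a network input tensor
#'
#' The per-image half of [prepare_batches()]: optional enhancement, scale
#' to `[0, 1]` by the source bit depth, bilinear resize to the plan's
#' input size and replication of the grayscale plane onto the requested
#' number of channels.
#'
#' @param img A [gray_image()].
#' @param plan A [build_plan()] result.
#' @param enhance If `TRUE`, run [enhance_image()] first.
#' @return A `(height, width, channels)` array in `[0, 1]`.
#' @export
image_to_input <- function(img, plan, enhance = FALSE) {
  if (enhance) img <- enhance_image(img)$enhanced
  maxv <- 2^img$bit_depth - 1
  m <- clamp01(img$pixels / maxv)
  H <- plan$input_size[1L]; W <- plan$input_size[2L]; C <- plan$input_size[3L]
  if (nrow(m) != H || ncol(m) != W) m <- warp_bilinear(m, H, W)
  array(rep(m, C), dim = c(H, W, C))
}

#' Prepare a batch stream from a dataset index
#'
#' Loads every image of the index (optionally enhancing each one first),
#' resizes to the plan's input size, replicates grayscale to the input
#' channels and one-hot encodes the labels in `class_names` order. A
#' training stream reshuffles and re-augments each epoch from seeds
#' derived from the plan seed, so identical seeds give identical pixel
#' streams; validation/test streams are fixed and unaugmented.
#'
#' @param index A [index_dataset()] result.
#' @param plan A [build_plan()] result; `plan$n_classes` must match the
#'   index's class count.
#' @param enhance If `TRUE`, pass every image through [enhance_image()].
#' @param training If `TRUE`, the stream shuffles and augments per epoch.
#' @return A `batch_stream`: list with the input array `x`
#'   (n, height, width, channels), one-hot `y`, `labels`, `class_names`
#'   and an `epoch_batches(epoch)` function returning the list of batches
#'   for that epoch.
#' @export
prepare_batches <- function(index, plan, enhance = FALSE, training = FALSE) {
  if (!inherits(index, "dataset_index")) stop("index must be a dataset_index")
  n <- nrow(index$entries)
  if (n == 0L) stop("dataset index is empty")
  if (length(index$class_names) != plan$n_classes)
    stop("index has ", length(index$class_names),
         " classes but the plan expects ", plan$n_classes)
  H <- plan$input_size[1L]; W <- plan$input_size[2L]; C <- plan$input_size[3L]
  x <- array(0, dim = c(n, H, W, C))
  for (i in seq_len(n))
    x[i, , , ] <- image_to_input(read_gray(index$entries$path[i]), plan,
                                 enhance = enhance)
  labels <- index$entries$class_label
  y <- matrix(0, n, plan$n_classes)
  y[cbind(seq_len(n), match(labels, index$class_names))] <- 1
  aug <- plan$augmentation
  bs <- plan$batch_size
  stream <- list(x = x, y = y, n = n, labels = labels,
                 class_names = index$class_names,
                 batch_size = bs, training = training,
                 seed = plan$seed)
  stream$epoch_batches <- function(epoch) {
    ord <- seq_len(n)
    xs <- x
    if (training) {
      with_seed(stable_hash(plan$seed, "epoch", epoch), {
        ord <- sample.int(n)
        for (i in seq_len(n)) {
          ang <- runif(1, -aug$rotation_deg, aug$rotation_deg)
          zm <- 1 + runif(1, -aug$zoom, aug$zoom)
          tx <- runif(1, -aug$translation, aug$translation) * W
          ty <- runif(1, -aug$translation, aug$translation) * H
          br <- 1 + runif(1, -aug$brightness, aug$brightness)
          flip <- aug$horizontal_flip && runif(1) < 0.5
          m <- xs[i, , , 1L]
          if (flip) m <- m[, rev(seq_len(ncol(m)))]
          m <- clamp01(br * warp_bilinear(m, H, W, ang, zm, tx, ty))
          xs[i, , , ] <- array(rep(m, C), dim = c(H, W, C))
        }
      })
    }
    starts <- seq(1L, n, by = bs)
    lapply(starts, function(s) {
      idx <- ord[s:min(s + bs - 1L, n)]
      list(x = xs[idx, , , , drop = FALSE], y = y[idx, , drop = FALSE])
    })
  }
  structure(stream, class = "batch_stream")
}

# Early-stopping / plateau bookkeeping: one state machine updated once
# per epoch with the monitored validation loss.
es_init <- function(patience, lr, factor, lr_patience, min_lr) {
  list(best = Inf, best_epoch = 0L, wait = 0L, lr_wait = 0L, stop = FALSE,
       patience = patience, lr = lr, factor = factor,
       lr_patience = lr_patience, min_lr = min_lr)
}

es_update <- function(st, val_loss, epoch) {
  if (val_loss < st$best - 1e-12) {
    st$best <- val_loss
    st$best_epoch <- epoch
    st$wait <- 0L
    st$lr_wait <- 0L
  } else {
    st$wait <- st$wait + 1L
    st$lr_wait <- st$lr_wait + 1L
    if (st$lr_wait >= st$lr_patience) {
      st$lr <- max(st$lr * st$factor, st$min_lr)
      st$lr_wait <- 0L
    }
    if (st$wait >= st$patience) st$stop <- TRUE
  }
  st
}

eval_stream <- function(layers, stream) {
  out <- forward_net(layers, stream$x, training = FALSE)
  sc <- softmax_ce(out, stream$y)
  acc <- mean(max.col(sc$probs, ties.method = "first") == max.col(stream$y, ties.method = "first"))
  list(loss = sc$loss, acc = acc, probs = sc$probs)
}

#' Train a classifier with the two-stage fine-tuning schedule
#'
#' Attaches a dropout + softmax head to the backbone's pooled feature
#' output and trains in two stages: stage 1 with every backbone layer
#' frozen at the stage-1 learning rate, stage 2 with the last
#' `unfreeze_last_n_layers` backbone layers trainable at the reduced
#' stage-2 rate. When a validation stream is given, each stage monitors
#' validation loss with plateau learning-rate reduction and early
#' stopping that restores the best weights. All randomness (head
#' initialization, dropout, shuffling, augmentation) derives from the
#' plan seed. The backbone's layers are updated in place.
#'
#' @param plan A [build_plan()] result.
#' @param backbone An `octnss_backbone` (see [backbone_tinycnn()]) whose
#'   input size matches the plan.
#' @param train_stream,val_stream [prepare_batches()] streams;
#'   `val_stream` may be `NULL` (no callbacks then).
#' @return An `octnss_model`: list with the layer stack, `class_names`,
#'   `plan`, and `history` (per-epoch data frame with stage, learning
#'   rate, train/val loss and accuracy), plus `best_epoch` and
#'   `stopped_early`.
#' @export
train_model <- function(plan, backbone, train_stream, val_stream = NULL) {
  if (!inherits(backbone, "octnss_backbone"))
    stop("backbone must be an octnss_backbone")
  if (!identical(as.integer(backbone$input_size),
                 as.integer(plan$input_size[1:2])))
    stop("backbone input size does not match the plan")
  history <- NULL
  best_epoch <- 0L
  stopped_early <- FALSE
  epoch_global <- 0L
  head <- NULL
  with_seed(plan$seed, {
    head <- list(layer_dropout(plan$dropout),
                 layer_dense(backbone$feature_dim, plan$n_classes,
                             init = "zero"))
  })
  all_layers <- c(backbone$layers, head)

  run_stage <- function(stage_id, lr0, epochs) {
    adam_init(all_layers)
    cb <- plan$callbacks
    st <- es_init(cb$early_stopping_patience, lr0, cb$reduce_lr_factor,
                  cb$reduce_lr_patience, cb$reduce_lr_min)
    snap_best <- snapshot_params(all_layers)
    t_adam <- 0L
    # backprop can stop below the deepest trainable layer
    trainable_idx <- which(vapply(all_layers,
                                  function(l) l$has_params && l$trainable,
                                  logical(1)))
    lowest <- if (length(trainable_idx)) min(trainable_idx) else 1L
    for (ep in seq_len(epochs)) {
      epoch_global <<- epoch_global + 1L
      batches <- train_stream$epoch_batches(epoch_global)
      tr_loss <- 0; tr_acc <- 0; n_seen <- 0L
      with_seed(stable_hash(plan$seed, "dropout", epoch_global), {
        for (bi in seq_along(batches)) {
          b <- batches[[bi]]
          out <- forward_net(all_layers, b$x, training = TRUE)
          sc <- softmax_ce(out, b$y)
          if (!is.finite(sc$loss))
            stop("non-finite training loss at stage ", stage_id,
                 ", epoch ", ep, ", batch ", bi)
          nb <- nrow(b$y)
          tr_loss <- tr_loss + sc$loss * nb
          tr_acc <- tr_acc + sum(max.col(sc$probs, ties.method = "first") == max.col(b$y, ties.method = "first"))
          n_seen <- n_seen + nb
          dy <- sc$dlogits
          for (li in rev(seq_along(all_layers))) {
            if (li < lowest) break
            dy <- backward_layer(all_layers[[li]], dy, want_dx = li > lowest)
          }
          t_adam <- t_adam + 1L
          adam_step(all_layers, st$lr, t_adam)
        }
      })
      val <- if (!is.null(val_stream)) eval_stream(all_layers, val_stream)
      history <<- rbind(history, data.frame(
        stage = stage_id, epoch = ep, lr = st$lr,
        train_loss = tr_loss / n_seen, train_acc = tr_acc / n_seen,
        val_loss = if (is.null(val)) NA_real_ else val$loss,
        val_acc = if (is.null(val)) NA_real_ else val$acc))
      if (!is.null(val)) {
        st <- es_update(st, val$loss, ep)
        if (st$best_epoch == ep) snap_best <- snapshot_params(all_layers)
        if (st$stop) {
          stopped_early <<- TRUE
          break
        }
      }
    }
    if (!is.null(val_stream) && plan$callbacks$early_stopping_restore_best &&
        st$best_epoch > 0L) {
      restore_params(all_layers, snap_best)
      best_epoch <<- nrow(history) - (nrow(history[history$stage == stage_id, ])) +
        st$best_epoch
    } else {
      best_epoch <<- nrow(history)
    }
  }

  freeze_all(backbone)
  for (l in head) l$trainable <- TRUE
  run_stage(1L, plan$stage1$lr, plan$stage1$epochs)
  unfreeze_last(backbone, plan$stage2$unfreeze_last_n_layers)
  run_stage(2L, plan$stage2$lr, plan$stage2$epochs)
  # with the final weights fixed, refresh BN running statistics on the
  # clean training inputs so inference matches the trained regime
  calibrate_bn(all_layers, train_stream$x, plan$batch_size)

  structure(list(layers = all_layers, backbone = backbone, head = head,
                 class_names = train_stream$class_names, plan = plan,
                 history = history, best_epoch = best_epoch,
                 stopped_early = stopped_early),
            class = "octnss_model")
}

#' Predict class probabilities
#'
#' @param object An `octnss_model` from [train_model()].
#' @param x A `(n, height, width, channels)` input array or a
#'   `batch_stream`.
#' @param ... Unused.
#' @return An n x K matrix of softmax probabilities with class-name
#'   columns.
#' @export
predict.octnss_model <- function(object, x, ...) {
  if (inherits(x, "batch_stream")) x <- x$x
  p <- softmax_probs(forward_net(object$layers, x, training = FALSE))
  colnames(p) <- object$class_names
  p
}

#' Evaluate a trained model on a test stream
#'
#' Runs the model over the stream and delegates to
#' [classification_report()] with argmax labels and softmax scores.
#'
#' @param model An `octnss_model`.
#' @param test_stream A [prepare_batches()] stream.
#' @return A `classification_report`.
#' @export
evaluate_model <- function(model, test_stream) {
  if (test_stream$n == 0L) stop("test stream is empty")
  probs <- predict(model, test_stream)
  preds <- test_stream$class_names[max.col(probs, ties.method = "first")]
  classification_report(test_stream$labels, preds, scores = probs,
                        class_names = test_stream$class_names)
}
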