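# Minimal neural-network layers in base R, enough to drive the two-stage
# fine-tuning harness at desk scale: 3x3 same-padding convolution (im2col),
# ReLU, 2x2 average pooling, global average pooling, inverted dropout and
# a dense layer, trained with Adam on a softmax cross-entropy head.
#
# Layers are environments so that parameters, Adam state and caches can be
# updated in place. Convolutional stages carry activations as
# (N, H, W, C) arrays; after global pooling activations are (N, F)
# matrices.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$trainable <- TRUE
  e$has_params <- FALSE
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e
}

layer_conv <- function(c_in, c_out, k = 3L) {
  fan_in <- k * k * c_in
  l <- new_layer("conv",
                 W = matrix(rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)),
                            fan_in, c_out),
                 b = rep(0, c_out),
                 k = k, c_in = c_in, c_out = c_out)
  l$has_params <- TRUE
  l
}

# The classifier head uses zero init: starting from uniform logits, every
# optimizer step moves along the class signal instead of fighting random
# projection noise, which matters at desk scale where stages run for only
# a handful of steps.
layer_dense <- function(n_in, n_out, init = c("he", "zero")) {
  init <- match.arg(init)
  W <- if (init == "zero") matrix(0, n_in, n_out)
  else matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  l <- new_layer("dense", W = W, b = rep(0, n_out))
  l$has_params <- TRUE
  l
}

layer_relu <- function() new_layer("relu")
layer_avgpool <- function() new_layer("avgpool")
layer_gap <- function() new_layer("gap")
layer_dropout <- function(p) new_layer("dropout", p = p)

# Batch normalization over the channel (last) axis; batch statistics in
# training mode, exponential running statistics at
# inference. gamma/beta are the trainable parameters (W/b slots so the
# Adam/snapshot machinery applies unchanged).
layer_batchnorm <- function(c_out, momentum = 0.7, eps = 1e-5) {
  l <- new_layer("batchnorm",
                 W = rep(1, c_out), b = rep(0, c_out),
                 running_mean = rep(0, c_out), running_var = rep(1, c_out),
                 momentum = momentum, eps = eps)
  l$has_params <- TRUE
  l
}

# im2col for a 3x3 (or k x k) same-padding convolution of one sample.
im2col <- function(x, k) {
  H <- dim(x)[1L]; W <- dim(x)[2L]; C <- dim(x)[3L]
  r <- (k - 1L) %/% 2L
  P <- array(0, dim = c(H + 2L * r, W + 2L * r, C))
  P[(r + 1L):(r + H), (r + 1L):(r + W), ] <- x
  cols <- matrix(0, H * W, k * k * C)
  idx <- 1L
  for (c in seq_len(C)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    cols[, idx] <- P[(1L + dy):(H + dy), (1L + dx):(W + dx), c]
    idx <- idx + 1L
  }
  cols
}

col2im <- function(dcols, H, W, C, k) {
  r <- (k - 1L) %/% 2L
  dP <- array(0, dim = c(H + 2L * r, W + 2L * r, C))
  idx <- 1L
  for (c in seq_len(C)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    dP[(1L + dy):(H + dy), (1L + dx):(W + dx), c] <-
      dP[(1L + dy):(H + dy), (1L + dx):(W + dx), c] + matrix(dcols[, idx], H, W)
    idx <- idx + 1L
  }
  dP[(r + 1L):(r + H), (r + 1L):(r + W), , drop = FALSE]
}

forward_layer <- function(l, x, training = FALSE) {
  switch(l$type,
    conv = {
      N <- dim(x)[1L]; H <- dim(x)[2L]; W <- dim(x)[3L]
      out <- array(0, dim = c(N, H, W, l$c_out))
      l$cache <- vector("list", N)
      l$in_dim <- dim(x)
      for (n in seq_len(N)) {
        cols <- im2col(array(x[n, , , ], dim = dim(x)[2:4]), l$k)
        l$cache[[n]] <- cols
        y <- cols %*% l$W + rep(l$b, each = H * W)
        out[n, , , ] <- array(y, dim = c(H, W, l$c_out))
      }
      out
    },
    relu = {
      l$mask <- x > 0
      x * l$mask
    },
    avgpool = {
      H <- dim(x)[2L]; W <- dim(x)[3L]
      if (H %% 2L != 0L || W %% 2L != 0L)
        stop("avgpool requires even spatial dimensions, got ", H, " x ", W)
      l$in_dim <- dim(x)
      o <- seq(1L, H, 2L); p <- seq(1L, W, 2L)
      0.25 * (x[, o, p, , drop = FALSE] + x[, o + 1L, p, , drop = FALSE] +
                x[, o, p + 1L, , drop = FALSE] + x[, o + 1L, p + 1L, , drop = FALSE])
    },
    gap = {
      l$in_dim <- dim(x)
      apply(x, c(1L, 4L), mean)
    },
    batchnorm = {
      d <- dim(x)
      C <- d[length(d)]
      xm <- matrix(x, ncol = C)
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        l$running_mean <- l$momentum * l$running_mean + (1 - l$momentum) * mu
        l$running_var <- l$momentum * l$running_var + (1 - l$momentum) * v
        inv <- 1 / sqrt(v + l$eps)
        xhat <- sweep(sweep(xm, 2L, mu), 2L, inv, "*")
        l$xhat <- xhat
        l$inv <- inv
        l$in_dim <- d
        y <- sweep(sweep(xhat, 2L, l$W, "*"), 2L, l$b, "+")
      } else {
        inv <- 1 / sqrt(l$running_var + l$eps)
        xhat <- sweep(sweep(xm, 2L, l$running_mean), 2L, inv, "*")
        y <- sweep(sweep(xhat, 2L, l$W, "*"), 2L, l$b, "+")
      }
      if (length(d) > 2L) array(y, dim = d) else y
    },
    dropout = {
      if (training && l$p > 0) {
        l$mask <- array(rbinom(length(x), 1L, 1 - l$p) / (1 - l$p), dim = dim(x))
        x * l$mask
      } else {
        l$mask <- NULL
        x
      }
    },
    dense = {
      l$cache <- x
      x %*% l$W + rep(l$b, each = nrow(x))
    },
    stop("unknown layer type: ", l$type))
}

backward_layer <- function(l, dy, want_dx = TRUE) {
  switch(l$type,
    conv = {
      N <- l$in_dim[1L]; H <- l$in_dim[2L]; W <- l$in_dim[3L]; C <- l$in_dim[4L]
      gW <- matrix(0, nrow(l$W), ncol(l$W))
      gb <- rep(0, length(l$b))
      dx <- if (want_dx) array(0, dim = l$in_dim) else NULL
      for (n in seq_len(N)) {
        dmat <- matrix(dy[n, , , ], H * W, l$c_out)
        gW <- gW + crossprod(l$cache[[n]], dmat)
        gb <- gb + colSums(dmat)
        if (want_dx)
          dx[n, , , ] <- col2im(tcrossprod(dmat, l$W), H, W, C, l$k)
      }
      if (l$trainable) { l$gW <- gW; l$gb <- gb }
      dx
    },
    relu = dy * l$mask,
    avgpool = {
      H <- l$in_dim[2L]; W <- l$in_dim[3L]
      dx <- array(0, dim = l$in_dim)
      o <- seq(1L, H, 2L); p <- seq(1L, W, 2L)
      g <- 0.25 * dy
      dx[, o, p, ] <- g; dx[, o + 1L, p, ] <- g
      dx[, o, p + 1L, ] <- g; dx[, o + 1L, p + 1L, ] <- g
      dx
    },
    gap = {
      H <- l$in_dim[2L]; W <- l$in_dim[3L]
      dx <- array(0, dim = l$in_dim)
      for (c in seq_len(l$in_dim[4L]))
        dx[, , , c] <- array(rep(dy[, c] / (H * W), H * W), dim = l$in_dim[1:3])
      dx
    },
    batchnorm = {
      d <- l$in_dim
      C <- d[length(d)]
      dym <- matrix(dy, ncol = C)
      if (l$trainable) {
        l$gW <- colSums(dym * l$xhat)
        l$gb <- colSums(dym)
      }
      # d x = gamma * inv * (dy - mean(dy) - xhat * mean(dy * xhat))
      mdy <- colMeans(dym)
      mdyx <- colMeans(dym * l$xhat)
      dxm <- sweep(dym, 2L, mdy) - sweep(l$xhat, 2L, mdyx, "*")
      dxm <- sweep(dxm, 2L, l$W * l$inv, "*")
      if (length(d) > 2L) array(dxm, dim = d) else dxm
    },
    dropout = if (is.null(l$mask)) dy else dy * l$mask,
    dense = {
      if (l$trainable) {
        l$gW <- crossprod(l$cache, dy)
        l$gb <- colSums(dy)
      }
      if (want_dx) tcrossprod(dy, l$W) else NULL
    },
    stop("unknown layer type: ", l$type))
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy loss and logit gradient for one batch.
softmax_ce <- function(logits, y) {
  p <- softmax_probs(logits)
  loss <- -mean(rowSums(y * log(pmax(p, 1e-12))))
  list(loss = loss, dlogits = (p - y) / nrow(y), probs = p)
}

# Adam state lives on each layer (mW/vW/mb/vb); `t` is the step counter.
adam_init <- function(layers) {
  for (l in layers) if (l$has_params) {
    l$mW <- l$W * 0; l$vW <- l$W * 0
    l$mb <- l$b * 0; l$vb <- l$b * 0
  }
  invisible(layers)
}

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) if (l$has_params && l$trainable && !is.null(l$gW)) {
    l$mW <- beta1 * l$mW + (1 - beta1) * l$gW
    l$vW <- beta2 * l$vW + (1 - beta2) * l$gW^2
    l$mb <- beta1 * l$mb + (1 - beta1) * l$gb
    l$vb <- beta2 * l$vb + (1 - beta2) * l$gb^2
    mhW <- l$mW / (1 - beta1^t); vhW <- l$vW / (1 - beta2^t)
    mhb <- l$mb / (1 - beta1^t); vhb <- l$vb / (1 - beta2^t)
    l$W <- l$W - lr * mhW / (sqrt(vhW) + eps)
    l$b <- l$b - lr * mhb / (sqrt(vhb) + eps)
    l$gW <- NULL; l$gb <- NULL
  }
  invisible(layers)
}

snapshot_params <- function(layers)
  lapply(layers, function(l) if (l$has_params)
    list(W = l$W, b = l$b,
         running_mean = l$running_mean, running_var = l$running_var))

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) if (!is.null(snap[[i]])) {
    layers[[i]]$W <- snap[[i]]$W
    layers[[i]]$b <- snap[[i]]$b
    if (!is.null(snap[[i]]$running_mean)) {
      layers[[i]]$running_mean <- snap[[i]]$running_mean
      layers[[i]]$running_var <- snap[[i]]$running_var
    }
  }
  invisible(layers)
}

#' Small convolutional backbone
#'
#' A three-block CNN in plain R for desk-scale experiments: three 3x3
#' convolution + batch-normalization + ReLU blocks (8, 16 and 32
#' filters), 2x2 average pooling after the first two blocks, global
#' average pooling and a final feature batch normalization, yielding a
#' 32-d pooled feature vector with roughly unit per-dimension scale (the
#' condition under which a freshly attached softmax head trains quickly).
#' It satisfies the backbone contract the training
#' harness expects: an ordered layer list, a pooled feature output, and
#' freeze-all / unfreeze-last-N operations ([freeze_all()],
#' [unfreeze_last()]). Any object with the same shape (e.g. a wrapper
#' around a large pretrained network) can be substituted.
#'
#' @param input_size `(height, width)` of the input, both divisible by 4.
#' @param in_channels Number of input channels, default 3.
#' @return An object of class `octnss_backbone`.
#' @export
backbone_tinycnn <- function(input_size = c(32L, 32L), in_channels = 3L) {
  if (any(input_size %% 4L != 0L))
    stop("tinycnn input dimensions must be divisible by 4")
  layers <- list(layer_conv(in_channels, 8L), layer_batchnorm(8L),
                 layer_relu(), layer_avgpool(),
                 layer_conv(8L, 16L), layer_batchnorm(16L),
                 layer_relu(), layer_avgpool(),
                 layer_conv(16L, 32L), layer_batchnorm(32L),
                 layer_relu(), layer_gap(), layer_batchnorm(32L))
  structure(list(layers = layers, feature_dim = 32L,
                 input_size = as.integer(input_size), name = "tinycnn"),
            class = "octnss_backbone")
}

#' Freeze all backbone layers
#'
#' Marks every parameterized layer non-trainable, the stage-1 state of
#' two-stage fine-tuning.
#'
#' @param backbone An `octnss_backbone`.
#' @return The backbone, invisibly (layers are modified in place).
#' @export
freeze_all <- function(backbone) {
  for (l in backbone$layers) l$trainable <- FALSE
  invisible(backbone)
}

#' Unfreeze the last N backbone layers
#'
#' Counts layers from the output end in the backbone's own enumeration
#' order (parameter-free layers count too, mirroring how deep-learning
#' frameworks enumerate layers) and marks them trainable.
#'
#' @param backbone An `octnss_backbone`.
#' @param n Number of layers, counted from the output end.
#' @return The backbone, invisibly (layers are modified in place).
#' @export
unfreeze_last <- function(backbone, n) {
  L <- length(backbone$layers)
  for (i in seq_len(L))
    backbone$layers[[i]]$trainable <- i > L - n
  invisible(backbone)
}

forward_net <- function(layers, x, training = FALSE) {
  for (l in layers) x <- forward_layer(l, x, training = training)
  x
}

# Precise-BN calibration: with the final weights fixed, replace each batch
# normalization layer's running statistics by the cumulative average of
# its batch statistics over the (unaugmented) training inputs, so that
# inference-mode normalization matches the data the head was trained on
# even when training ran for only a few steps.
calibrate_bn <- function(layers, x, batch_size) {
  bn <- Filter(function(l) l$type == "batchnorm", layers)
  if (length(bn) == 0L) return(invisible(NULL))
  for (l in bn) {
    l$mom_save <- l$momentum
    l$t_cal <- 0L
  }
  n <- dim(x)[1L]
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    xb <- x[idx, , , , drop = FALSE]
    for (l in bn) {
      l$t_cal <- l$t_cal + 1L
      l$momentum <- 1 - 1 / l$t_cal
    }
    for (l in layers) {
      if (l$type == "dropout") next
      xb <- forward_layer(l, xb, training = l$type == "batchnorm")
    }
  }
  for (l in bn) l$momentum <- l$mom_save
  invisible(NULL)
}
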