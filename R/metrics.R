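# Image quality metrics (PSNR, SSIM, Shannon entropy, entropy improvement)
# and multi-class classification reports.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in decibels. Identical images have
#' zero MSE and report `Inf` rather than an error, since comparing an
#' image against itself is a legitimate degenerate case.
#'
#' @param ref,test Numeric matrices of the same shape.
#' @param data_range Peak-to-peak data range, default 255 for 8-bit.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(ref, test, data_range = 255) {
  ref <- as_pixels(ref); test <- as_pixels(test)
  if (!identical(dim(ref), dim(test)))
    stop("ref and test must have the same shape")
  mse <- mean((as.numeric(ref) - as.numeric(test))^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# 1-D Gaussian taps, radius 5 / sigma 1.5, normalized; together with its
# transpose this is the standard 11 x 11 SSIM window.
ssim_gauss <- function(sigma = 1.5, radius = 5L) {
  g <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable 'valid' correlation with a symmetric 1-D kernel along both
# axes; output shrinks by 2*radius in each dimension.
filter_valid <- function(m, g) {
  r <- (length(g) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W - 2L * r)
  for (k in seq_along(g)) out <- out + g[k] * m[, k:(W - 2L * r + k - 1L)]
  out2 <- matrix(0, H - 2L * r, W - 2L * r)
  for (k in seq_along(g)) out2 <- out2 + g[k] * out[k:(H - 2L * r + k - 1L), ]
  out2
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM in the standard Wang et al. parameterization: Gaussian
#' window of size 11 with sigma 1.5, `K1 = 0.01`, `K2 = 0.03`, data range
#' 255, Gaussian-weighted (population) moments, averaged over the valid
#' region (no padding).
#'
#' @param ref,test Numeric matrices of the same shape, at least 11 x 11.
#' @param data_range Data range, default 255.
#' @return The mean SSIM, a number in `[-1, 1]`.
#' @export
ssim <- function(ref, test, data_range = 255) {
  x <- as_pixels(ref); y <- as_pixels(test)
  if (!identical(dim(x), dim(y)))
    stop("ref and test must have the same shape")
  if (nrow(x) < 11L || ncol(x) < 11L)
    stop("images must be at least 11 x 11 for the SSIM window")
  g <- ssim_gauss()
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mx <- filter_valid(x, g)
  my <- filter_valid(y, g)
  vx <- filter_valid(x * x, g) - mx^2
  vy <- filter_valid(y * y, g) - my^2
  cxy <- filter_valid(x * y, g) - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Shannon entropy of an 8-bit raster
#'
#' `-sum(p_k log2 p_k)` over the 256-bin histogram, with `0 * log 0 = 0`.
#' Constant images have 0 bits; a raster using all 256 values equally
#' often has 8 bits.
#'
#' @param img8 Matrix (or [gray_image()]) with integer values in `0..255`.
#' @return Entropy in bits, in `[0, 8]`.
#' @export
shannon_entropy <- function(img8) {
  m <- as_pixels(img8)
  if (length(m) == 0L) stop("empty raster")
  if (any(!is.finite(m)) || any(m < 0) || any(m > 255) || any(m != floor(m)))
    stop("img8 must hold integers in 0..255")
  h <- tabulate(as.integer(m) + 1L, 256L)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Relative entropy improvement in percent
#'
#' `100 * (h_enh - h_orig) / h_orig`, the summary used to quantify how
#' much textural information an enhancement added.
#'
#' @param h_orig Entropy of the original image in bits; must be positive.
#' @param h_enh Entropy of the enhanced image in bits.
#' @return Improvement in percent (positive when entropy increased).
#' @examples
#' entropy_improvement(6.1010, 6.9122)  # +13.3 when rounded to one decimal
#' @export
entropy_improvement <- function(h_orig, h_enh) {
  if (!is.numeric(h_orig) || h_orig <= 0)
    stop("h_orig must be positive")
  100 * (h_enh - h_orig) / h_orig
}

#' Format an entropy improvement as printed in reports
#'
#' One decimal with a leading sign, e.g. `"+13.3%"`.
#'
#' @param pct Improvement percentage from [entropy_improvement()].
#' @return A character string.
#' @export
format_improvement <- function(pct) sprintf("%+.1f%%", pct)

# Render an image to 8-bit counts for histogram/PSNR/SSIM purposes.
# 8-bit sources are used as-is (rounded and clamped); 16-bit sources are
# scaled down by 257 so both renderings share the 0..255 scale.
render_8bit <- function(img) {
  if (inherits(img, "gray_image") && img$bit_depth > 8L)
    return(clamp(round_half_away(img$pixels / 257), 0, 255))
  clamp(round_half_away(as_pixels(img)), 0, 255)
}

#' Image quality report for an original/enhanced pair
#'
#' Computes PSNR, SSIM, the Shannon entropies of the 8-bit renderings of
#' both images and the relative entropy improvement, as one data-frame
#' row.
#'
#' @param orig,enh Original and enhanced images ([gray_image()] or
#'   matrices on the 0..255 scale).
#' @return A one-row `data.frame` with columns `psnr_db`, `ssim`,
#'   `entropy_orig`, `entropy_enh`, `entropy_improvement_pct`.
#' @export
quality_report <- function(orig, enh) {
  o8 <- render_8bit(orig)
  e8 <- render_8bit(enh)
  ho <- shannon_entropy(o8)
  he <- shannon_entropy(e8)
  data.frame(
    psnr_db = psnr(o8, e8),
    ssim = ssim(o8, e8),
    entropy_orig = ho,
    entropy_enh = he,
    entropy_improvement_pct = if (ho > 0) entropy_improvement(ho, he) else NA_real_)
}

#' Multi-class classification report
#'
#' Confusion matrix (rows = true class), per-class precision/recall/F1
#' with supports, support-weighted headline averages, overall accuracy
#' and, when class probability scores are supplied, one-vs-rest ROC AUC
#' per class computed by the trapezoidal rule.
#'
#' @param y_true,y_pred Character or factor vectors of equal length.
#' @param scores Optional numeric matrix of per-class probabilities, one
#'   row per sample and one column per class (in `class_names` order);
#'   rows must sum to 1 within `1e-6`.
#' @param class_names Ordered class labels; defaults to the sorted union
#'   of the observed labels. Labels outside this set are an error.
#' @return A `classification_report`: list with `accuracy`, `precision_w`,
#'   `recall_w`, `f1_w`, `per_class` (data frame), `confusion` (K x K
#'   integer matrix) and `auc_ovr` (named vector or `NULL`).
#' @export
classification_report <- function(y_true, y_pred, scores = NULL,
                                  class_names = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) == 0L)
    stop("y_true and y_pred must be nonempty and of equal length")
  if (is.null(class_names))
    class_names <- sort(unique(c(y_true, y_pred)), method = "radix")
  bad <- setdiff(unique(c(y_true, y_pred)), class_names)
  if (length(bad) > 0L)
    stop("labels outside the class set: ", paste(bad, collapse = ", "))
  K <- length(class_names)
  conf <- table(factor(y_true, levels = class_names),
                factor(y_pred, levels = class_names))
  conf <- matrix(as.integer(conf), K, K,
                 dimnames = list(true = class_names, pred = class_names))
  tp <- diag(conf)
  support <- rowSums(conf)
  predicted <- colSums(conf)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  n <- length(y_true)
  auc <- NULL
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (nrow(scores) != n || ncol(scores) != K)
      stop("scores must be an n x K probability matrix")
    if (any(abs(rowSums(scores) - 1) > 1e-6))
      stop("score rows must sum to 1 within 1e-6")
    auc <- vapply(seq_len(K), function(k) {
      resp <- y_true == class_names[k]
      if (!any(resp) || all(resp)) return(NA_real_)
      r <- pROC::roc(response = resp, predictor = scores[, k],
                     levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
      as.numeric(pROC::auc(r))
    }, numeric(1))
    names(auc) <- class_names
  }
  structure(
    list(accuracy = sum(tp) / n,
         precision_w = sum(precision * support) / n,
         recall_w = sum(recall * support) / n,
         f1_w = sum(f1 * support) / n,
         per_class = data.frame(class = class_names, precision = precision,
                                recall = recall, f1 = f1, support = support,
                                row.names = NULL),
         confusion = conf,
         auc_ovr = auc),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> accuracy %.4f | weighted P %.4f R %.4f F1 %.4f\n",
    x$accuracy, x$precision_w, x$recall_w, x$f1_w))
  print(x$per_class, digits = 4)
  if (!is.null(x$auc_ovr)) {
    cat("one-vs-rest AUC:\n")
    print(round(x$auc_ovr, 4))
  }
  invisible(x)
}
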