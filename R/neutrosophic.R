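# Neutrosophic-domain transform: normalization, Sobel gradients, T/I/F
# membership maps and the per-pixel similarity score against the ideal
# alternative (T, I, F) = (1, 0, 0).

#' Neutrosophic transform parameters
#'
#' @param epsilon Small positive constant guarding the min-max
#'   denominators against division by zero. Default `1e-8`.
#' @return An object of class `neutro_params`.
#' @export
neutro_params <- function(epsilon = 1e-8) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a single positive number")
  structure(list(epsilon = epsilon), class = "neutro_params")
}

#' Min-max normalize an image to [0, 1)
#'
#' `IN = (I - Imin) / (Imax - Imin + epsilon)` with `Imin`/`Imax` the
#' observed minimum and maximum of the pixel raster itself. A constant
#' image maps to all zeros (the numerator vanishes while the denominator
#' stays at `epsilon`).
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param params A [neutro_params()].
#' @return A numeric matrix with values in `[0, 1)`.
#' @export
normalize_image <- function(img, params = neutro_params()) {
  p <- as_pixels(img)
  if (any(!is.finite(p))) stop("pixels must be finite")
  mn <- min(p)
  mx <- max(p)
  (p - mn) / (mx - mn + params$epsilon)
}

#' Sobel gradient magnitude
#'
#' Cross-correlates the raster with the 3 x 3 Sobel kernels
#' `Sx = [-1 0 1; -2 0 2; -1 0 1]` and `Sy = t(Sx)` and returns
#' `Gd = sqrt(Gx^2 + Gy^2)`. Borders are handled by replicate
#' (edge-clamp) padding so that flat images stay flat and no spurious
#' border edges appear.
#'
#' @param norm Numeric matrix, at least 3 x 3 (typically the output of
#'   [normalize_image()]).
#' @return A `gradient_map`: list with the magnitude raster `Gd` and its
#'   recorded extrema `gd_min`, `gd_max`.
#' @export
gradient_magnitude <- function(norm) {
  if (!is.matrix(norm) || !is.numeric(norm))
    stop("norm must be a numeric matrix")
  H <- nrow(norm)
  W <- ncol(norm)
  if (H < 3 || W < 3)
    stop("raster must be at least 3 x 3 for the Sobel kernels")
  P <- norm[c(1L, seq_len(H), H), c(1L, seq_len(W), W)]  # replicate pad
  S <- function(dy, dx) P[(1L + dy):(H + dy), (1L + dx):(W + dx)]
  Gx <- -S(0L, 0L) + S(0L, 2L) - 2 * S(1L, 0L) + 2 * S(1L, 2L) -
    S(2L, 0L) + S(2L, 2L)
  Gy <- -S(0L, 0L) - 2 * S(0L, 1L) - S(0L, 2L) +
    S(2L, 0L) + 2 * S(2L, 1L) + S(2L, 2L)
  Gd <- sqrt(Gx^2 + Gy^2)
  structure(list(Gd = Gd, gd_min = min(Gd), gd_max = max(Gd)),
            class = "gradient_map")
}

#' Truth / indeterminacy / falsity membership maps
#'
#' Maps a normalized image and its gradient magnitudes into the
#' neutrosophic domain: `T` is the normalized intensity, `I` is one minus
#' the min-max-normalized gradient magnitude (flat regions are maximally
#' indeterminate), and `F = 1 - T`. The gradient normalization gets the
#' same epsilon guard as the intensity normalization, so a constant image
#' yields `I = 1` everywhere. All maps are clamped to `[0, 1]`.
#'
#' @param norm Numeric matrix in `[0, 1)` from [normalize_image()].
#' @param grad A `gradient_map` from [gradient_magnitude()].
#' @param params A [neutro_params()].
#' @return A `neutro_maps`: list with matrices `T`, `I`, `F`.
#' @export
tif_maps <- function(norm, grad, params = neutro_params()) {
  if (!inherits(grad, "gradient_map")) stop("grad must be a gradient_map")
  if (!identical(dim(norm), dim(grad$Gd)))
    stop("shape mismatch between norm (", paste(dim(norm), collapse = "x"),
         ") and gradient map (", paste(dim(grad$Gd), collapse = "x"), ")")
  Tm <- clamp01(norm)
  Im <- clamp01(1 - (grad$Gd - grad$gd_min) /
                  (grad$gd_max - grad$gd_min + params$epsilon))
  structure(list(T = Tm, I = Im, F = 1 - Tm), class = "neutro_maps")
}

#' Cosine similarity of two neutrosophic triples
#'
#' The similarity of two alternatives `a = (Ta, Ia, Fa)` and
#' `b = (Tb, Ib, Fb)` is their normalized inner product
#' `(Ta*Tb + Ia*Ib + Fa*Fb) / (|a| |b|)`, which is 1 for identical
#' directions and 0 for orthogonal ones. With `b = (1, 0, 0)` this is the
#' per-pixel similarity-to-ideal score that [nss_map()] vectorizes.
#'
#' @param a,b Numeric length-3 vectors with components in `[0, 1]`,
#'   neither all-zero.
#' @return A single number in `[0, 1]`.
#' @examples
#' pairwise_similarity(c(1, 0, 0), c(0.5, 0.5, 0.5))
#' @export
pairwise_similarity <- function(a, b) {
  for (v in list(a, b)) {
    if (!is.numeric(v) || length(v) != 3L)
      stop("triples must be numeric vectors of length 3")
    if (any(v < 0 | v > 1)) stop("triple components must lie in [0, 1]")
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("similarity is undefined for a zero-norm triple")
  sum(a * b) / (na * nb)
}

#' Neutrosophic similarity score map
#'
#' Scores every pixel's `(T, I, F)` triple against the ideal alternative
#' `(1, 0, 0)`, which collapses the cosine similarity to
#' `S = T / sqrt(T^2 + I^2 + F^2)`. Because `F = 1 - T` the denominator
#' can never vanish, but it is guarded by `epsilon` regardless.
#'
#' @param maps A `neutro_maps` from [tif_maps()].
#' @param params A [neutro_params()].
#' @return An `nss_map`: list with the score raster `S` in `[0, 1]`.
#' @export
nss_map <- function(maps, params = neutro_params()) {
  if (!inherits(maps, "neutro_maps")) stop("maps must be a neutro_maps")
  d <- sqrt(maps$T^2 + maps$I^2 + maps$F^2)
  S <- clamp01(maps$T / pmax(d, params$epsilon))
  structure(list(S = S), class = "nss_map")
}
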