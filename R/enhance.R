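# End-to-end enhancement: NSS map -> 8-bit quantization -> CLAHE ->
# renormalization -> defuzzification back to the source intensity range.

#' Enhancement parameters
#'
#' @param epsilon Division-by-zero guard shared with the neutrosophic
#'   stages. Default `1e-8`.
#' @param alpha Scale from the `[0, 1]` similarity map to 8-bit counts.
#'   Default 255.
#' @param clahe_clip CLAHE clip limit, a multiple of the mean per-tile
#'   histogram bin count. Default 2.0.
#' @param clahe_tiles Integer `(rows, cols)` tile grid. Default `c(8, 8)`.
#' @return An object of class `enhance_params`.
#' @export
enhance_params <- function(epsilon = 1e-8, alpha = 255,
                           clahe_clip = 2.0, clahe_tiles = c(8L, 8L)) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (alpha <= 0) stop("alpha must be positive")
  if (clahe_clip <= 0) stop("clahe_clip must be positive")
  clahe_tiles <- as.integer(clahe_tiles)
  if (length(clahe_tiles) != 2L || any(clahe_tiles < 1L))
    stop("clahe_tiles must be two integers >= 1")
  structure(list(epsilon = epsilon, alpha = alpha, clahe_clip = clahe_clip,
                 clahe_tiles = clahe_tiles),
            class = "enhance_params")
}

#' Quantize a [0, 1] raster to 8-bit counts
#'
#' `v -> round(alpha * v)` with half rounded away from zero, clamped to
#' `[0, 255]`.
#'
#' @param map01 Numeric matrix with values in `[0, 1]`.
#' @param alpha Scale factor, default 255.
#' @return An integer matrix with values in `0..255`.
#' @export
quantize_8bit <- function(map01, alpha = 255) {
  if (!is.matrix(map01) || !is.numeric(map01))
    stop("map01 must be a numeric matrix")
  if (any(!is.finite(map01)) || any(map01 < -1e-9) || any(map01 > 1 + 1e-9))
    stop("map01 values must lie in [0, 1]")
  q <- round_half_away(alpha * clamp01(map01))
  q <- clamp(q, 0, 255)
  storage.mode(q) <- "integer"
  q
}

#' Contrast-limited adaptive histogram equalization
#'
#' Classic tile-based CLAHE on an 8-bit raster: the image is divided into
#' a `tiles` grid (padded by edge replication when the dimensions do not
#' divide evenly), a 256-bin histogram is built per tile and clipped at
#' `clip` times the mean bin count, the clipped excess is redistributed
#' uniformly (with the remainder spread one count at a time), each tile's
#' cumulative histogram becomes an equalization mapping onto `[0, 255]`,
#' and every pixel is bilinearly interpolated between the mappings of the
#' four surrounding tile centers (clamped at the borders).
#'
#' @param img8 Integer-valued matrix with values in `0..255`.
#' @param clip Clip limit as a multiple of the mean bin count. Default 2.
#' @param tiles Integer `(rows, cols)` tile grid. Default `c(8, 8)`.
#' @return An integer matrix in `0..255` with the same shape as `img8`.
#' @export
apply_clahe <- function(img8, clip = 2.0, tiles = c(8L, 8L)) {
  if (!is.matrix(img8) || !is.numeric(img8))
    stop("img8 must be a numeric matrix")
  if (any(!is.finite(img8)) || any(img8 < 0) || any(img8 > 255) ||
      any(img8 != floor(img8)))
    stop("img8 must hold integers in 0..255")
  tiles <- as.integer(tiles)
  if (length(tiles) != 2L || any(tiles < 1L))
    stop("tiles must be two integers >= 1 (degenerate tile geometry)")
  if (clip <= 0) stop("clip must be positive")
  H <- nrow(img8); W <- ncol(img8)
  ty <- tiles[1L]; tx <- tiles[2L]
  Hp <- ceiling(H / ty) * ty
  Wp <- ceiling(W / tx) * tx
  m <- img8
  if (Hp > H) m <- rbind(m, m[rep(H, Hp - H), , drop = FALSE])
  if (Wp > W) m <- cbind(m, m[, rep(W, Wp - W), drop = FALSE])
  th <- Hp %/% ty; tw <- Wp %/% tx
  area <- th * tw
  nbins <- 256L
  cl <- max(1, floor(clip * area / nbins))

  luts <- array(0, dim = c(ty, tx, nbins))
  for (i in seq_len(ty)) for (j in seq_len(tx)) {
    tile <- m[((i - 1L) * th + 1L):(i * th), ((j - 1L) * tw + 1L):(j * tw)]
    h <- tabulate(as.integer(tile) + 1L, nbins)
    h <- clip_histogram(h, cl)
    luts[i, j, ] <- pmin(255, 255 * cumsum(h) / area)
  }

  # Bilinear interpolation between tile-center mappings, clamped at borders.
  gy <- (seq_len(Hp) - 0.5) / th - 0.5
  gx <- (seq_len(Wp) - 0.5) / tw - 0.5
  i0 <- clamp(floor(gy), 0, ty - 1L)
  fy <- gy - floor(gy); fy[gy < 0 | gy > ty - 1L] <- 0
  i1 <- pmin(i0 + 1L, ty - 1L)
  j0 <- clamp(floor(gx), 0, tx - 1L)
  fx <- gx - floor(gx); fx[gx < 0 | gx > tx - 1L] <- 0
  j1 <- pmin(j0 + 1L, tx - 1L)

  V <- as.integer(m) + 1L                      # column-major bin indices
  I0 <- rep(i0 + 1L, times = Wp); I1 <- rep(i1 + 1L, times = Wp)
  FY <- rep(fy, times = Wp)
  J0 <- rep(j0 + 1L, each = Hp); J1 <- rep(j1 + 1L, each = Hp)
  FX <- rep(fx, each = Hp)
  g <- function(I, J) luts[cbind(I, J, V)]
  out <- (1 - FY) * ((1 - FX) * g(I0, J0) + FX * g(I0, J1)) +
    FY * ((1 - FX) * g(I1, J0) + FX * g(I1, J1))
  out <- round_half_away(matrix(out, Hp, Wp)[seq_len(H), seq_len(W)])
  storage.mode(out) <- "integer"
  out
}

# Clip a histogram at `cl` counts per bin and redistribute the excess:
# first a uniform increment to every low bin, then the remainder one count
# at a time over progressively offset scans of the bins.
clip_histogram <- function(h, cl) {
  nbins <- length(h)
  excess <- sum(pmax(h - cl, 0))
  if (excess == 0) return(h)
  incr <- excess %/% nbins
  upper <- cl - incr
  over <- h > cl
  high <- !over & h > upper
  low <- !over & !high
  excess <- excess - sum(h[high] - upper) - sum(low) * incr
  h[over | high] <- cl
  h[low] <- h[low] + incr
  start <- 1L
  while (excess > 0) {
    step <- max(1L, nbins %/% excess)
    k <- start
    while (k <= nbins && excess > 0) {
      if (h[k] < cl) {
        h[k] <- h[k] + 1L
        excess <- excess - 1L
      }
      k <- k + step
    }
    start <- if (start >= nbins) 1L else start + 1L
  }
  h
}

#' Map an equalized [0, 1] raster back to the source intensity range
#'
#' Defuzzification is the affine map
#' `out = e_norm * (orig_max - orig_min) + orig_min`. A degenerate range
#' (`orig_min == orig_max`) yields a constant output regardless of
#' `e_norm`, which is what makes constant images fixed points of the full
#' pipeline.
#'
#' @param e_norm Numeric matrix in `[0, 1]`.
#' @param orig_min,orig_max Intensity range recorded at read time.
#' @return A numeric matrix with values in `[orig_min, orig_max]`.
#' @export
defuzzify <- function(e_norm, orig_min, orig_max) {
  if (!is.matrix(e_norm) || !is.numeric(e_norm))
    stop("e_norm must be a numeric matrix")
  if (any(!is.finite(e_norm)) || any(e_norm < -1e-9) || any(e_norm > 1 + 1e-9))
    stop("e_norm values must lie in [0, 1]")
  if (orig_min > orig_max) stop("orig_min must not exceed orig_max")
  clamp01(e_norm) * (orig_max - orig_min) + orig_min
}

#' Enhance a grayscale OCT image in the neutrosophic domain
#'
#' Runs the full pipeline: min-max normalization, Sobel gradient
#' magnitudes, truth/indeterminacy/falsity maps, per-pixel similarity to
#' the ideal pixel `(1, 0, 0)`, 8-bit quantization, CLAHE, division by 255
#' and defuzzification back to the image's recorded intensity range. The
#' result is a pure function of the pixels and parameters: two calls on
#' the same input are bit-identical.
#'
#' @param img A [gray_image()] (or numeric matrix, which is wrapped with
#'   its observed range and 8-bit depth).
#' @param params An [enhance_params()].
#' @param keep_intermediates If `TRUE`, retain the `T`, `I`, `F`, `S`
#'   rasters and the 8-bit stages for inspection.
#' @return An `enhance_result`: list with `enhanced` (a [gray_image()]
#'   whose values lie within the source range), `e_norm` (the equalized
#'   `[0, 1]` raster), `params_used` and optional `intermediates`.
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 1))
#' res <- enhance_image(ph)
#' range(res$enhanced$pixels)
#' @export
enhance_image <- function(img, params = enhance_params(),
                          keep_intermediates = FALSE) {
  if (!inherits(img, "gray_image")) img <- gray_image(as_pixels(img))
  np <- neutro_params(params$epsilon)
  norm <- normalize_image(img, np)
  grad <- gradient_magnitude(norm)
  maps <- tif_maps(norm, grad, np)
  S <- nss_map(maps, np)$S
  q <- quantize_8bit(S, params$alpha)
  e8 <- apply_clahe(q, params$clahe_clip, params$clahe_tiles)
  e_norm <- e8 / 255
  out <- defuzzify(e_norm, img$orig_min, img$orig_max)
  enhanced <- gray_image(out, img$orig_min, img$orig_max,
                         source_path = img$source_path,
                         bit_depth = img$bit_depth)
  structure(
    list(enhanced = enhanced, e_norm = e_norm, params_used = params,
         intermediates = if (keep_intermediates)
           list(T = maps$T, I = maps$I, F = maps$F, S = S,
                nss8 = q, clahe8 = e8)),
    class = "enhance_result")
}

#' Enhance every image under a directory tree
#'
#' Mirrors the directory layout of `in_root` under `out_root`, enhancing
#' each image file and writing the 8-bit rendering of the result. JPEG
#' sources are written as PNG (the writer refuses lossy output).
#'
#' @param in_root Directory containing images (arbitrarily nested, e.g. a
#'   class-folder dataset).
#' @param out_root Output directory, created if needed.
#' @param params An [enhance_params()].
#' @return Invisibly, the character vector of files written.
#' @export
batch_enhance <- function(in_root, out_root, params = enhance_params()) {
  if (!dir.exists(in_root)) stop("input directory does not exist: ", in_root)
  rel <- list.files(in_root, recursive = TRUE)
  rel <- rel[tolower(tools::file_ext(rel)) %in% IMAGE_EXTENSIONS]
  if (length(rel) == 0L) stop("no image files under: ", in_root)
  written <- character(length(rel))
  for (k in seq_along(rel)) {
    img <- read_gray(file.path(in_root, rel[k]))
    res <- enhance_image(img, params)
    # 16-bit sources are rendered to 8-bit from the equalized [0,1] raster
    out_px <- if (img$bit_depth > 8L) 255 * res$e_norm else res$enhanced$pixels
    dst <- file.path(out_root, rel[k])
    if (tolower(tools::file_ext(dst)) %in% c("jpg", "jpeg"))
      dst <- paste0(tools::file_path_sans_ext(dst), ".png")
    dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
    write_gray(out_px, dst)
    written[k] <- dst
  }
  invisible(written)
}
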