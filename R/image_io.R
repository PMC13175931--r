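# Reading, writing and indexing of grayscale OCT images.

IMAGE_EXTENSIONS <- c("png", "tif", "tiff", "jpg", "jpeg")

#' Grayscale image container
#'
#' A `gray_image` bundles a 2-D intensity raster with the intensity range
#' recorded at read time (`orig_min`/`orig_max`, the `Imin`/`Imax` that
#' defuzzification maps back to) and the source bit depth. Every stage of
#' the enhancement pipeline consumes and produces this type.
#'
#' @param pixels Numeric matrix of intensities (rows = image rows). Must be
#'   at least 3 x 3 because the Sobel stage needs a full 3 x 3 neighborhood.
#' @param orig_min,orig_max Recorded intensity range. Default to the
#'   observed `min`/`max` of `pixels`. Must bracket the pixel values.
#' @param source_path Optional path the image was read from.
#' @param bit_depth Source bit depth, 8 or 16.
#' @return An object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' img$orig_max
#' @export
gray_image <- function(pixels, orig_min = NULL, orig_max = NULL,
                       source_path = NULL, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("pixels must be finite")
  if (nrow(pixels) < 3 || ncol(pixels) < 3)
    stop("image must be at least 3 x 3, got ",
         nrow(pixels), " x ", ncol(pixels))
  if (!bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16")
  if (is.null(orig_min)) orig_min <- min(pixels)
  if (is.null(orig_max)) orig_max <- max(pixels)
  if (orig_min > orig_max) stop("orig_min must not exceed orig_max")
  if (orig_min > min(pixels) || orig_max < max(pixels))
    stop("recorded range [", orig_min, ", ", orig_max,
         "] does not bracket the pixel values")
  structure(
    list(pixels = pixels, orig_min = orig_min, orig_max = orig_max,
         source_path = source_path, bit_depth = as.integer(bit_depth)),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d-bit, range [%g, %g]%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$orig_min, x$orig_max,
              if (is.null(x$source_path)) "" else paste0(" from ", x$source_path)))
  invisible(x)
}

# Bit depth of a PNG from its IHDR chunk (byte 25 of the file). Depths
# below 8 are expanded to 8 by the decoder and reported as 8.
png_bit_depth <- function(path) {
  b <- readBin(path, "raw", n = 25L)
  d <- as.integer(b[25L])
  if (identical(d, 16L)) 16L else 8L
}

#' Read an image as a grayscale raster
#'
#' Decodes a PNG, TIFF or JPEG file to a [gray_image()]. Color inputs are
#' converted to luma by the ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel, if present, is dropped.
#' Pixel values are reported on the source integer scale (0..255 for 8-bit,
#' 0..65535 for 16-bit) and the observed min/max are recorded.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return A [gray_image()].
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_gray(gray_image(matrix(0:255, 16, 16)), f)
#' read_gray(f)
#' @export
read_gray <- function(path) {
  if (!file.exists(path))
    stop("cannot read image, no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  dec <- tryCatch(
    switch(ext,
           png  = list(arr = png::readPNG(path), bits = png_bit_depth(path)),
           tif  = ,
           tiff = {
             x <- tiff::readTIFF(path, info = TRUE)
             bps <- attr(x, "bits.per.sample")
             list(arr = x, bits = if (identical(as.integer(bps), 16L)) 16L else 8L)
           },
           jpg  = ,
           jpeg = list(arr = jpeg::readJPEG(path), bits = 8L),
           stop("unsupported image format '", ext, "': ", path)),
    error = function(e) stop("failed to decode image ", path, ": ",
                             conditionMessage(e)))
  maxval <- 2^dec$bits - 1
  arr <- dec$arr
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      g <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      g <- arr[, , 1L]  # gray + alpha
    }
  } else {
    g <- arr
  }
  px <- round_half_away(g * maxval)
  if (!is.matrix(px) || nrow(px) < 3 || ncol(px) < 3)
    stop("image too small (need at least 3 x 3): ", path)
  gray_image(px, min(px), max(px), source_path = path, bit_depth = dec$bits)
}

#' Write a grayscale raster as an 8-bit image
#'
#' Values are clamped to `[0, 255]` and rounded half away from zero before
#' encoding, so a read-back of a written 8-bit image reproduces the rounded
#' values exactly. The container is chosen from the file extension (PNG or
#' TIFF; JPEG is refused because it is lossy).
#'
#' @param img A [gray_image()] or numeric matrix with finite values.
#' @param path Destination path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  m <- as_pixels(img)
  if (any(!is.finite(m))) stop("pixel values must be finite")
  m <- round_half_away(clamp(m, 0, 255))
  ext <- tolower(tools::file_ext(path))
  tryCatch(
    switch(ext,
           png  = png::writePNG(m / 255, path),
           tif  = ,
           tiff = tiff::writeTIFF(m / 255, path, bits.per.sample = 8L),
           stop("unsupported output format '", ext,
                "' (use .png or .tiff): ", path)),
    error = function(e) stop("failed to write image ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

#' Index a class-folder dataset split
#'
#' Walks `<root>/<split>/<CLASS>/...` and enumerates every image file,
#' producing a deterministic index: class names are sorted in C-locale
#' (radix) order, entries are sorted by full path, and files with
#' unrecognized extensions are skipped with a warning.
#'
#' @param root Dataset root containing `train`/`val`/`test` directories.
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @return A `dataset_index`: list with `root`, `split`, `entries` (data
#'   frame of `path`, `class_label`), `class_names` and per-class `counts`.
#' @export
index_dataset <- function(root, split = c("train", "val", "test")) {
  split <- match.arg(split)
  dir <- file.path(root, split)
  if (!dir.exists(dir))
    stop("split directory does not exist: ", dir)
  classes <- sort(basename(list.dirs(dir, recursive = FALSE)), method = "radix")
  if (length(classes) == 0L)
    stop("empty split directory (no class subdirectories): ", dir)
  paths <- character(0)
  labels <- character(0)
  n_skipped <- 0L
  for (cl in classes) {
    fs <- sort(list.files(file.path(dir, cl), full.names = TRUE),
               method = "radix")
    ok <- tolower(tools::file_ext(fs)) %in% IMAGE_EXTENSIONS
    n_skipped <- n_skipped + sum(!ok)
    paths <- c(paths, fs[ok])
    labels <- c(labels, rep(cl, sum(ok)))
  }
  if (n_skipped > 0L)
    warning("skipped ", n_skipped, " file(s) with non-image extensions under ", dir)
  if (length(paths) == 0L)
    stop("no image files found under: ", dir)
  ord <- order(paths, method = "radix")
  entries <- data.frame(path = paths[ord], class_label = labels[ord],
                        stringsAsFactors = FALSE)
  counts <- vapply(classes, function(cl) sum(entries$class_label == cl), integer(1))
  structure(list(root = root, split = split, entries = entries,
                 class_names = classes, counts = counts),
            class = "dataset_index")
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index> split '%s': %d images, %d classes\n",
              x$split, nrow(x$entries), length(x$class_names)))
  print(x$counts)
  invisible(x)
}
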