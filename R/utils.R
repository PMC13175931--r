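# Internal numeric helpers shared across modules.

# Round half away from zero (the bracket convention used throughout:
# 127.5 -> 128, -0.5 -> -1). base::round() rounds half to even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Deterministic, platform-independent hash of arbitrary tokens onto
# [0, 2^31 - 2]; used to derive per-image seeds from (seed, split, class, k).
stable_hash <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Extract the pixel matrix from a gray_image or pass a plain matrix through.
as_pixels <- function(img) {
  if (inherits(img, "gray_image")) return(img$pixels)
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected a 'gray_image' or a numeric matrix, got ", class(img)[1])
}
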