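# Independent straight-line oracles, written as naive per-pixel loops so
# they share no code path with the vectorized package implementation.

oracle_round <- function(x) sign(x) * floor(abs(x) + 0.5)

# Per-tile CLAHE with explicit loops (clip at clip * tileArea / 256
# floored to at least 1, two-phase excess redistribution, continuous
# equalization LUTs, bilinear interpolation between tile centers).
oracle_clahe <- function(img8, clip = 2, tiles = c(8L, 8L)) {
  H <- nrow(img8); W <- ncol(img8)
  ty <- tiles[1]; tx <- tiles[2]
  Hp <- ceiling(H / ty) * ty; Wp <- ceiling(W / tx) * tx
  m <- matrix(0L, Hp, Wp)
  for (y in 1:Hp) for (x in 1:Wp) m[y, x] <- img8[min(y, H), min(x, W)]
  th <- Hp / ty; tw <- Wp / tx
  area <- th * tw
  cl <- max(1, floor(clip * area / 256))
  luts <- vector("list", ty * tx)
  for (i in 1:ty) for (j in 1:tx) {
    h <- integer(256)
    for (y in ((i - 1) * th + 1):(i * th)) for (x in ((j - 1) * tw + 1):(j * tw))
      h[m[y, x] + 1] <- h[m[y, x] + 1] + 1L
    excess <- 0
    for (b in 1:256) if (h[b] > cl) excess <- excess + h[b] - cl
    if (excess > 0) {
      incr <- excess %/% 256
      upper <- cl - incr
      for (b in 1:256) {
        if (h[b] > cl) h[b] <- cl
        else if (h[b] > upper) { excess <- excess - (h[b] - upper); h[b] <- cl }
        else { excess <- excess - incr; h[b] <- h[b] + incr }
      }
      start <- 1
      while (excess > 0) {
        step <- max(1, 256 %/% excess)
        b <- start
        while (b <= 256 && excess > 0) {
          if (h[b] < cl) { h[b] <- h[b] + 1L; excess <- excess - 1 }
          b <- b + step
        }
        start <- if (start >= 256) 1 else start + 1
      }
    }
    lut <- numeric(256)
    cum <- 0
    for (b in 1:256) { cum <- cum + h[b]; lut[b] <- min(255, 255 * cum / area) }
    luts[[(i - 1) * tx + j]] <- lut
  }
  out <- matrix(0L, H, W)
  for (y in 1:H) for (x in 1:W) {
    gy <- (y - 0.5) / th - 0.5
    gx <- (x - 0.5) / tw - 0.5
    i0 <- min(max(floor(gy), 0), ty - 1)
    fy <- gy - floor(gy); if (gy < 0 || gy > ty - 1) fy <- 0
    i1 <- min(i0 + 1, ty - 1)
    j0 <- min(max(floor(gx), 0), tx - 1)
    fx <- gx - floor(gx); if (gx < 0 || gx > tx - 1) fx <- 0
    j1 <- min(j0 + 1, tx - 1)
    v <- m[y, x] + 1
    lu <- luts[[i0 * tx + j0 + 1]][v]; ru <- luts[[i0 * tx + j1 + 1]][v]
    lb <- luts[[i1 * tx + j0 + 1]][v]; rb <- luts[[i1 * tx + j1 + 1]][v]
    out[y, x] <- oracle_round((1 - fy) * ((1 - fx) * lu + fx * ru) +
                                fy * ((1 - fx) * lb + fx * rb))
  }
  storage.mode(out) <- "integer"
  out
}

# Straight-line transliteration of the whole enhancement recipe:
# normalization, Sobel magnitudes with edge-clamped loops, T/I/F,
# similarity to (1,0,0), 8-bit quantization, CLAHE, defuzzification.
oracle_enhance <- function(px, eps = 1e-8, alpha = 255,
                           clip = 2, tiles = c(8L, 8L)) {
  H <- nrow(px); W <- ncol(px)
  Imin <- min(px); Imax <- max(px)
  IN <- (px - Imin) / (Imax - Imin + eps)
  Sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  Sy <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)
  Gd <- matrix(0, H, W)
  for (y in 1:H) for (x in 1:W) {
    gx <- 0; gy <- 0
    for (dy in -1:1) for (dx in -1:1) {
      yy <- min(max(y + dy, 1), H)
      xx <- min(max(x + dx, 1), W)
      gx <- gx + Sx[dy + 2, dx + 2] * IN[yy, xx]
      gy <- gy + Sy[dy + 2, dx + 2] * IN[yy, xx]
    }
    Gd[y, x] <- sqrt(gx^2 + gy^2)
  }
  gmin <- min(Gd); gmax <- max(Gd)
  S <- matrix(0, H, W)
  for (y in 1:H) for (x in 1:W) {
    Tv <- min(max(IN[y, x], 0), 1)
    Iv <- min(max(1 - (Gd[y, x] - gmin) / (gmax - gmin + eps), 0), 1)
    Fv <- 1 - Tv
    S[y, x] <- min(max(Tv / max(sqrt(Tv^2 + Iv^2 + Fv^2), eps), 0), 1)
  }
  q <- matrix(0L, H, W)
  for (y in 1:H) for (x in 1:W)
    q[y, x] <- min(max(oracle_round(alpha * S[y, x]), 0), 255)
  storage.mode(q) <- "integer"
  e8 <- oracle_clahe(q, clip, tiles)
  enhanced <- e8 / 255 * (Imax - Imin) + Imin
  list(nss8 = q, clahe8 = e8, enhanced = enhanced)
}
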