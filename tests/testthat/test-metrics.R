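test_that("psnr follows its closed form and degenerate conventions", {
  m <- random_raster8(16, 16)
  expect_identical(psnr(m, m), Inf)
  expect_equal(psnr(matrix(0, 3, 3), matrix(255, 3, 3)), 0)
  # MSE of exactly 1 at range 255: 20*log10(255)
  m3 <- m + 1 - 2 * (m == 255)
  expect_equal(psnr(m, m3), 20 * log10(255), tolerance = 1e-10)
  expect_equal(psnr(m, m3), 48.1308, tolerance = 1e-3)
  expect_error(psnr(m, matrix(0, 4, 4)), "shape")
  # symmetry
  a <- random_raster8(12, 12); b <- random_raster8(12, 12)
  expect_equal(psnr(a, b), psnr(b, a))
})

test_that("ssim matches identity, zero-variance closed form and symmetry", {
  m <- random_raster8(32, 32)
  expect_equal(ssim(m, m), 1)
  C1 <- (0.01 * 255)^2
  expect_equal(ssim(matrix(50, 16, 16), matrix(120, 16, 16)),
               (2 * 50 * 120 + C1) / (50^2 + 120^2 + C1), tolerance = 1e-12)
  a <- random_raster8(24, 24); b <- random_raster8(24, 24)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "11 x 11")
})

test_that("ssim reproduces reference values on frozen fixtures", {
  # expected values computed with scikit-image structural_similarity
  # (gaussian_weights=TRUE, use_sample_covariance=FALSE, win_size=11,
  # data_range=255) on these exact seeded rasters
  set.seed(404)
  a <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  b <- pmin(pmax(a + round(rnorm(64 * 64, 0, 20)), 0), 255)
  expect_equal(ssim(a, b), 0.9655668661539801, tolerance = 1e-6)
  set.seed(808)
  c1 <- matrix(round(127 + 60 * sin(outer(1:64, 1:64, "+") / 9) +
                       rnorm(4096, 0, 15)), 64, 64)
  c1 <- pmin(pmax(c1, 0), 255)
  d1 <- pmin(pmax(round(c1 * 0.8 + 20), 0), 255)
  expect_equal(ssim(c1, d1), 0.9759331177377351, tolerance = 1e-6)
})

test_that("shannon_entropy matches counting arguments", {
  expect_equal(shannon_entropy(matrix(9, 10, 10)), 0)
  expect_equal(shannon_entropy(matrix(0:255, 16, 16)), 8)
  expect_equal(shannon_entropy(matrix(c(0, 255), 16, 16)), 1)
  # two unequal masses: -(p log2 p + q log2 q)
  m <- matrix(0, 10, 10); m[1:25] <- 255
  expect_equal(shannon_entropy(m), -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  expect_error(shannon_entropy(matrix(256, 3, 3)), "0..255")
})

test_that("entropy improvement reproduces the published class-wise table", {
  pairs <- list(
    AMD = c(6.3862, 6.6257, 3.8), CNV = c(6.4183, 6.7601, 5.3),
    CSR = c(6.1010, 6.9122, 13.3), DME = c(6.4086, 6.7254, 4.9),
    DR = c(6.4847, 7.0187, 8.2), DRUSEN = c(6.7238, 7.0891, 5.4),
    MH = c(6.2679, 6.9252, 10.5), NORMAL = c(6.1746, 6.5823, 6.6))
  for (p in pairs) {
    expect_equal(round(entropy_improvement(p[1], p[2]), 1), p[3])
  }
  expect_equal(entropy_improvement(5.5, 5.5), 0)
  expect_error(entropy_improvement(0, 1), "positive")
  expect_equal(format_improvement(entropy_improvement(6.1010, 6.9122)),
               "+13.3%")
})

test_that("quality_report bundles the four metrics consistently", {
  ph <- generate_phantom(phantom_spec(height = 64, width = 64,
                                      contrast_preset = "low", seed = 21))
  enh <- enhance_image(ph)$enhanced
  qr <- quality_report(ph, enh)
  expect_equal(qr$entropy_improvement_pct,
               entropy_improvement(qr$entropy_orig, qr$entropy_enh))
  expect_true(qr$entropy_orig >= 0 && qr$entropy_orig <= 8)
  expect_true(is.finite(qr$psnr_db))
  expect_true(qr$ssim >= -1 && qr$ssim <= 1)
})

test_that("classification_report matches hand-computed confusion arithmetic", {
  # perfect predictions, 3 classes x 4 samples
  y <- rep(c("a", "b", "c"), each = 4)
  rep1 <- classification_report(y, y)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$per_class$f1, rep(1, 3))
  expect_equal(diag(rep1$confusion), c(a = 4L, b = 4L, c = 4L))

  # 2-class confusion [[3,1],[2,4]]
  yt <- c(rep("neg", 4), rep("pos", 6))
  yp <- c("neg", "neg", "neg", "pos", "neg", "neg", "pos", "pos", "pos", "pos")
  r <- classification_report(yt, yp)
  expect_equal(unname(r$confusion["neg", ]), c(3L, 1L))
  expect_equal(unname(r$confusion["pos", ]), c(2L, 4L))
  expect_equal(r$accuracy, 0.7)
  expect_equal(r$per_class$precision[1], 0.6)
  expect_equal(r$per_class$recall[1], 0.75)
  # row sums equal supports; accuracy is the diagonal mass
  expect_equal(unname(rowSums(r$confusion)), c(4L, 6L))
  expect_equal(r$accuracy, sum(diag(r$confusion)) / 10)
  expect_error(classification_report(yt, yp, class_names = c("neg")),
               "outside")
})

test_that("weighted F1 equals the support-weighted mean of per-class F1", {
  set.seed(33)
  cls <- c("u", "v", "w", "x")
  yt <- sample(cls, 200, TRUE, prob = c(0.5, 0.25, 0.15, 0.1))
  yp <- ifelse(runif(200) < 0.6, yt, sample(cls, 200, TRUE))
  r <- classification_report(yt, yp, class_names = cls)
  expect_equal(r$f1_w,
               sum(r$per_class$f1 * r$per_class$support) /
                 sum(r$per_class$support),
               tolerance = 1e-12)
})

test_that("one-vs-rest AUC is 1 for one-hot scores and validates inputs", {
  y <- rep(c("a", "b", "c"), times = 5)
  sc <- diag(3)[match(y, c("a", "b", "c")), ]
  r <- classification_report(y, y, scores = sc, class_names = c("a", "b", "c"))
  expect_equal(unname(r$auc_ovr), c(1, 1, 1))
  bad <- sc; bad[1, ] <- c(0.5, 0.2, 0.2)
  expect_error(classification_report(y, y, scores = bad), "sum to 1")
})
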