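test_that("intensity normalization is the exact affine min-max map", {
  g <- gray_image(matrix(c(2, 4, 6, 4), 2), 1, 1)
  expect_equal(sort(unique(c(normalize_intensity(g)$pixels))), c(0, 0.5, 1))

  unit <- gray_image(matrix(c(0, 0.25, 1, 0.5), 2), 1, 1)
  expect_equal(normalize_intensity(unit)$pixels, unit$pixels)

  set.seed(1)
  m <- matrix(sample(0:255, 120, replace = TRUE), 10)
  out <- normalize_intensity(gray_image(m, 1, 1))$pixels
  expect_equal(out, (m - min(m)) / (max(m) - min(m)))

  expect_error(normalize_intensity(gray_image(matrix(3, 4, 4), 1, 1)),
               "constant")
})

test_that("resolution homogenization upsamples the coarse axis and preserves extent", {
  # native-resolution raster: 256 x 1024 px over 8 mm x 16 mm
  set.seed(2)
  g <- gray_image(matrix(runif(256 * 1024), 256), 0.015625, 0.03125)
  h <- homogenize_resolution(g)
  expect_identical(dim(h$pixels), c(512L, 1024L))
  expect_equal(h$px_mm_x, h$px_mm_y)
  expect_equal(h$px_mm_x, 0.015625)

  iso <- gray_image(matrix(runif(64), 8), 0.1, 0.1)
  expect_identical(dim(homogenize_resolution(iso)$pixels), c(8L, 8L))

  const <- gray_image(matrix(0.7, 8, 8), 0.1, 0.2)
  expect_true(all(homogenize_resolution(const)$pixels == 0.7))
})

test_that("rectangular median filter matches a brute-force window oracle", {
  const <- gray_image(matrix(0.4, 9, 9), 1, 1)
  expect_equal(median_filter_mm(const, c(3, 3))$pixels, const$pixels)

  z <- matrix(0, 9, 9); z[5, 5] <- 1
  expect_true(all(median_filter_mm(gray_image(z, 1, 1), c(3, 3))$pixels == 0))

  set.seed(3)
  m <- matrix(runif(12 * 15), 12, 15)
  out <- median_filter_mm(gray_image(m, 1, 1), c(3, 5))$pixels
  # oracle: edge-replicated padding + explicit window medians
  rh <- 1; rw <- 2
  pad <- m[pmin(pmax(seq_len(12 + 2 * rh) - rh, 1), 12),
           pmin(pmax(seq_len(15 + 2 * rw) - rw, 1), 15)]
  oracle <- matrix(NA_real_, 12, 15)
  for (i in seq_len(12)) for (j in seq_len(15))
    oracle[i, j] <- median(pad[i:(i + 2 * rh), j:(j + 2 * rw)])
  expect_equal(out, oracle)

  expect_warning(tiny <- median_filter_mm(gray_image(m, 1, 1), c(0.2, 0.2)),
                 "unchanged")
  expect_equal(tiny$pixels, m)
})

test_that("anisotropic diffusion matches the direct-loop update and is range-bounded", {
  g0 <- gray_image(matrix(runif(16), 4), 1, 1)
  expect_equal(anisotropic_diffusion(g0, n_iter = 0L)$pixels, g0$pixels)

  const <- gray_image(matrix(0.3, 6, 6), 1, 1)
  expect_equal(anisotropic_diffusion(const, 10L)$pixels, const$pixels)

  set.seed(4)
  m <- matrix(runif(32 * 32), 32)
  got <- anisotropic_diffusion(gray_image(m, 1, 1), 7L, kappa = 0.15,
                               lam = 0.2)$pixels
  expect_lt(max(abs(got - pm_oracle(m, 7L, 0.15, 0.2))), 1e-10)
  expect_gte(min(got), min(m)); expect_lte(max(got), max(m))

  expect_error(anisotropic_diffusion(g0, 5L, lam = 0.3), "stability")
})

test_that("diffusion preserves a strong step edge while smoothing the flats", {
  set.seed(5)
  m <- matrix(0.1, 16, 64)
  m[, 33:64] <- 0.9
  m <- m + matrix(rnorm(16 * 64, sd = 0.02), 16)
  sm <- anisotropic_diffusion(gray_image(m, 1, 1), 10L, kappa = 0.1,
                              lam = 0.25)$pixels
  # edge stays where the row-wise |gradient| peaks
  grad_pos <- apply(abs(sm[, -1] - sm[, -64]), 1, which.max)
  expect_true(all(grad_pos == 32))
  # each flat region gets strictly smoother
  expect_lt(var(c(sm[, 1:28])), var(c(m[, 1:28])))
  expect_lt(var(c(sm[, 37:64])), var(c(m[, 37:64])))
})

test_that("raw moments, centroid and covariance match Eq-style brute force", {
  ones <- compute_moments(gray_image(matrix(1, 3, 3), 1, 1))
  expect_equal(ones$S, 9)
  expect_equal(unname(ones$centroid), c(1, 1))
  expect_equal(ones$cov, diag(c(2 / 3, 2 / 3)))

  z <- matrix(0, 7, 5); z[3, 4] <- 2.5
  single <- compute_moments(gray_image(z, 1, 1))
  expect_equal(unname(single$centroid), c(2, 3))
  expect_equal(single$cov, matrix(0, 2, 2))

  set.seed(6)
  m <- matrix(sample(0:9, 100, replace = TRUE), 10)
  got <- compute_moments(gray_image(m, 1, 1))
  exp <- moments_oracle(m)
  for (f in names(exp)) expect_identical(got[[f]], exp[[f]])

  expect_error(compute_moments(matrix(0, 4, 4)), "S = 0")
})

test_that("alignment centers, levels the principal axis, and zero-fills", {
  # horizontal bright bar already centered: near-identity alignment
  bar <- matrix(0, 32, 64)
  bar[15:18, 10:55] <- 1
  a <- align(gray_image(bar, 1, 1))
  expect_identical(dim(a$canvas), c(64L, 128L))
  expect_lt(abs(a$rotation_deg), 1e-6)

  mo <- compute_moments(a$canvas)
  expect_lt(max(abs(mo$centroid - (dim(a$canvas) - 1) / 2)), 1)
  ev <- eigen(mo$cov, symmetric = TRUE)$vectors[, 1]
  expect_lt(abs(atan2(ev[1], ev[2]) * 180 / pi) %% 180, 1)

  # rotated copy aligns back onto the original
  g <- gray_image(bar, 1, 1)
  rot <- transform_image(g, rotation_deg = 30)
  a2 <- align(rot)
  expect_gte(cor(c(a$canvas), c(a2$canvas)), 0.95)

  # untouched canvas pixels are exactly zero
  expect_identical(sum(a$canvas[1:5, ]), 0)
})

test_that("alignment is idempotent and pose-invariant on phantoms", {
  p <- test_phantom_params(speckle_sigma = 0, background_level = 0)
  img <- generate_phantom(p)
  a0 <- preprocess_image(img)
  set.seed(7)
  for (k in 1:3) {
    th <- runif(1, -15, 15); sh <- round(runif(2, -6, 6))
    ak <- preprocess_image(transform_image(img, th, sh))
    expect_gte(cor(c(a0$canvas), c(ak$canvas)), 0.95)
  }
  # second alignment pass is a near no-op
  a1 <- align(gray_image(a0$canvas, a0$px_mm, a0$px_mm))
  expect_lte(abs(a1$rotation_deg), 1)
  expect_lte(max(abs(a1$centroid - (dim(a0$canvas) - 1) / 2)), 1)
})

test_that("rotationally symmetric mass triggers the identity-rotation fallback", {
  n <- 41
  d <- sqrt(outer((1:n - 21)^2, (1:n - 21)^2, "+"))
  disc <- 1 * (d <= 10)
  expect_warning(a <- align(gray_image(disc, 1, 1)), "identity")
  expect_equal(a$rotation_deg, 0)
})
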