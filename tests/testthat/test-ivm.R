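test_that("corrected integrated density applies dark/area/reference/AF in order", {
  px <- matrix(5, 20, 20)            # uniform image equal to dark current
  img <- fluorescence_image(px, pixel_area = 100, channel = "nir",
                            dark_current = 5)
  roi <- matrix(TRUE, 20, 20)
  expect_equal(corrected_density(img, roi)$integrated_density, 0)

  # dark + 10 over an ROI of exactly 5000 um^2: brute-force summation oracle
  img2 <- fluorescence_image(matrix(15, 20, 20), pixel_area = 100,
                             channel = "nir", dark_current = 5)
  roi2 <- matrix(FALSE, 20, 20); roi2[1:10, 1:5] <- TRUE  # 50 px * 100 um^2
  m <- corrected_density(img2, roi2)
  oracle <- sum(img2$pixels[roi2] - 5) * 5000 / (50 * 100)
  expect_equal(m$integrated_density, oracle)
  expect_equal(m$n_pixels, 50)

  # reference factor 2 halves the corrected value exactly (AF = 0)
  img3 <- img2; img3$reference_factor <- 2
  expect_equal(corrected_density(img3, roi2)$integrated_density, oracle / 2)

  # autofluorescence larger than the signal clips at zero with a flag
  img4 <- img2; img4$autofluorescence <- 1e6
  m4 <- corrected_density(img4, roi2)
  expect_equal(m4$integrated_density, 0)
  expect_true(m4$clipped)
  expect_error(corrected_density(img2, matrix(FALSE, 20, 20)), "empty")
})

test_that("SD-weighted mean follows the inverse-variance formula", {
  # equal SDs reduce exactly to the arithmetic mean
  w <- weighted_mean_sd(c(3, 7, 11), c(2, 2, 2))
  expect_identical(w$wmean, mean(c(3, 7, 11)))
  # hand arithmetic: values {10, 20}, sds {1, 2}
  w2 <- weighted_mean_sd(c(10, 20), c(1, 2))
  expect_equal(w2$wmean, 12)
  expect_equal(w2$wsd, sqrt(0.8))
  # single value
  w3 <- weighted_mean_sd(5, 0.3)
  expect_equal(w3$wmean, 5)
  expect_equal(w3$wsd, 0.3)
  # zero SDs are capped at the smallest positive SD, not infinite weight
  w4 <- weighted_mean_sd(c(1, 3), c(0, 2))
  expect_equal(w4$wmean, weighted_mean_sd(c(1, 3), c(2, 2))$wmean)
  # weighted mean lies between min and max
  set.seed(31)
  for (i in 1:25) {
    v <- rnorm(6); s <- runif(6, 0.1, 2)
    wm <- weighted_mean_sd(v, s)$wmean
    expect_gte(wm, min(v)); expect_lte(wm, max(v))
  }
  expect_error(weighted_mean_sd(numeric(0), numeric(0)))
})

test_that("tumor-to-normal ratio propagates first-order uncertainty", {
  t_ <- weighted_mean_sd(c(30, 30), c(3, 3), spread = "sample")
  n_ <- weighted_mean_sd(c(10, 10), c(1, 1), spread = "sample")
  t_$wsd <- 3; n_$wsd <- 1   # 30 +/- 3 over 10 +/- 1
  r <- tnr(t_, n_)
  expect_equal(r$ratio, 3)
  expect_equal(r$sd, sqrt((3 / 10)^2 + (30 * 1 / 100)^2))
  expect_equal(tnr(t_, t_)$ratio, 1)
  zero <- weighted_mean_sd(0, 1)
  expect_error(tnr(t_, zero), "positive")
})

test_that("constructed 3x contrast yields a TNR of 3 within noise tolerance", {
  set.seed(41)
  mk <- function(level) {
    vals <- replicate(4, mean(level + rnorm(200, sd = 0.05 * level)))
    sds <- replicate(4, sd(level + rnorm(200, sd = 0.05 * level)))
    weighted_mean_sd(vals, sds)
  }
  r <- tnr(mk(30), mk(10))
  expect_equal(r$ratio, 3, tolerance = 0.05)
})

test_that("Spearman colocalization equals the rank-then-Pearson oracle", {
  set.seed(13)
  g <- fluorescence_image(matrix(runif(50), 10, 5), 1, "gfp",
                          dark_current = 0.1)
  r <- fluorescence_image(matrix(runif(50), 10, 5), 1, "nir",
                          dark_current = 0.2)
  res <- spearman_coloc(g, r)
  expect_equal(res$rho, brute_spearman(g$pixels, r$pixels), tolerance = 1e-12)
  expect_equal(res$n_pixels, 50)

  # monotone transform of the same image -> rho = 1; antitone -> -1
  r_mono <- fluorescence_image(exp(2 * g$pixels) + 3, 1, "nir")
  expect_equal(spearman_coloc(g, r_mono)$rho, 1)
  r_anti <- fluorescence_image(-g$pixels, 1, "nir")
  expect_equal(spearman_coloc(g, r_anti)$rho, -1)

  # invariance under strictly increasing per-channel transforms
  rho0 <- spearman_coloc(g, r)$rho
  g2 <- fluorescence_image(g$pixels^3 + 1, 1, "gfp")
  r2 <- fluorescence_image(log(r$pixels + 2), 1, "nir")
  expect_equal(spearman_coloc(g2, r2)$rho, rho0, tolerance = 1e-12)

  const <- fluorescence_image(matrix(1, 10, 5), 1, "nir")
  expect_true(is.na(spearman_coloc(g, const)$rho))
  expect_error(spearman_coloc(g, r, roi = c(1, 2)), ">= 3")
})

test_that("colocalization rises monotonically with the shared-structure fraction", {
  lv <- seq(0, 1, length.out = 10)
  rho <- vapply(lv, function(f) {
    pair <- simulate_coloc_pair(n = 48, coloc_fraction = f, seed = 7)
    spearman_coloc(pair$green, pair$red)$rho
  }, numeric(1))
  expect_equal(cor(lv, rho, method = "spearman"), 1)
  expect_gt(rho[10], 0.9)
  expect_lt(rho[1], 0.5)
})
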