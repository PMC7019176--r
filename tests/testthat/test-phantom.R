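test_that("AIF is zero pre-injection, sums amplitudes at onset, then decays", {
  aif <- aif_params()
  expect_equal(aif_concentration(119, aif, t0 = 120), 0)
  expect_equal(aif_concentration(120, aif, t0 = 120), 5.36 + 1.27)
  # term-by-term independent evaluation at t0 + 60 s
  expect_equal(aif_concentration(180, aif, t0 = 120),
               5.36 * exp(-60 / 5.36) + 1.27 * exp(-60 / 915),
               tolerance = 1e-12)
  tt <- seq(120, 900, by = 0.5)
  expect_true(all(diff(aif_concentration(tt, aif, t0 = 120)) <= 0))
  expect_error(aif_params(tau1 = -1))
  expect_error(aif_params(tau1 = 10, tau2 = 5))
})

test_that("closed-form Tofts curve matches the discrete-convolution oracle", {
  tt <- seq(0, 900, by = 3.5)
  cf <- tissue_concentration(tt, 0.25, 0.4, t0 = 120)
  or <- disc_conv_tofts(tt, 0.25, 0.4, t0 = 120)
  expect_lt(max(abs(cf - or)), 1e-4)

  # degenerate point kep = 1/tau1 exactly: no division blow-up
  aif <- aif_params()
  ve <- 0.35
  kt_deg <- 60 * ve / aif$tau1
  cf_deg <- tissue_concentration(tt, kt_deg, ve, aif, t0 = 120)
  expect_true(all(is.finite(cf_deg)))
  expect_lt(max(abs(cf_deg - disc_conv_tofts(tt, kt_deg, ve, aif, 120))),
            1e-4)

  # random parameter draws
  set.seed(42)
  for (i in 1:20) {
    kt <- runif(1, 0.01, 1); ve <- runif(1, 0.1, 0.6)
    expect_lt(max(abs(tissue_concentration(tt, kt, ve, t0 = 120) -
                        disc_conv_tofts(tt, kt, ve, t0 = 120))), 1e-4)
  }
})

test_that("tissue_concentration input contracts hold", {
  tt <- seq(0, 400, by = 3.5)
  expect_equal(tissue_concentration(tt, 0, 0.4, t0 = 120), rep(0, length(tt)))
  expect_error(tissue_concentration(tt, 0.2, 0, t0 = 120))
  expect_error(tissue_concentration(tt, 0.2, 1.5, t0 = 120))
})

test_that("SPGR signal has the correct limits and closed form", {
  expect_lt(spgr_signal(1000, 1.5, 1e-9, 0.02), 1e-6)       # sin(alpha) -> 0
  expect_equal(spgr_signal(1000, 0.001, 30, 1e3), 500,      # full recovery
               tolerance = 1e-6)
  e1 <- exp(-0.02 / 1.5)
  a <- 7 * pi / 180
  expect_equal(spgr_signal(1000, 1.5, 7, 0.02),
               1000 * sin(a) * (1 - e1) / (1 - e1 * cos(a)),
               tolerance = 1e-12)
  expect_error(spgr_signal(1000, -1, 7, 0.02))
})

test_that("phantom truth maps satisfy their invariants", {
  tr <- small_truth()
  expect_true(all(tr$nonenhanced_core_mask[] <= tr$tumor_mask[]))  # subset
  expect_true(all(tr$ktrans_map[tr$nonenhanced_core_mask] == 0))
  pk <- tr$ktrans_map > 0
  expect_true(all(tr$ve_map[pk] > 0 & tr$ve_map[pk] <= 1))
  expect_true(all(tr$t1_map[tr$tissue_mask] > 0))
  rim <- tr$tumor_mask & !tr$nonenhanced_core_mask
  expect_true(all(tr$ktrans_map[rim] >= 0.01 & tr$ktrans_map[rim] <= 1))
})

test_that("simulation is reproducible under a fixed seed and noise obeys its model", {
  tr <- small_truth()
  ns <- noise_spec("rician", sigma = 2, seed = 7)
  s1 <- simulate_study(tr, noise = ns)
  s2 <- simulate_study(tr, noise = ns)
  expect_identical(s1$dce$signal, s2$dce$signal)
  expect_identical(s1$vfa$signal, s2$vfa$signal)
  s3 <- simulate_study(tr, noise = noise_spec("rician", sigma = 2, seed = 8))
  expect_false(identical(s3$dce$signal, s2$dce$signal))

  # Rician mean of a zero-signal voxel is sigma * sqrt(pi/2)
  z <- add_noise(array(0, c(100, 100, 1)), noise_spec("rician", 3, seed = 1))
  expect_equal(mean(z), 3 * sqrt(pi / 2), tolerance = 0.02)
  # Gaussian noise is unbiased and scales correctly
  g <- add_noise(array(10, c(100, 100, 1)),
                 noise_spec("gaussian", 3, seed = 1))
  expect_equal(mean(g), 10, tolerance = 0.02)
  expect_equal(sd(g), 3, tolerance = 0.05)
})

test_that("noise addition leaves the caller's RNG stream untouched", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(add_noise(array(0, c(5, 5, 1)), noise_spec("rician", 1, seed = 2)))
  after <- runif(3)
  expect_identical(before, after)
})
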