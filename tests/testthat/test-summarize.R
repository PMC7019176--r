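test_that("non-enhanced fraction is exact set arithmetic", {
  d <- c(10, 10, 3)
  enh <- array(TRUE, d)
  roi <- array(FALSE, d); roi[1:5, 1:4, ] <- TRUE
  expect_equal(nonenhanced_fraction(enh, roi), 0)
  enh[1:5, 1:2, ] <- FALSE   # half the ROI
  expect_equal(nonenhanced_fraction(enh, roi), 50)
  # complement identity holds exactly
  enhanced_fraction <- 100 * sum(enh & roi) / sum(roi)
  expect_identical(nonenhanced_fraction(enh, roi) + enhanced_fraction, 100)
  expect_error(nonenhanced_fraction(enh, array(FALSE, d)), "empty")
})

test_that("central-slice selection follows the middle-four rule", {
  d <- c(20, 20, 16)
  tum <- array(FALSE, d)
  tum[8:12, 5:9, 5:12] <- TRUE    # slices 5..12 -> central four are 7..10
  rs <- place_muscle_rois(tum, beam_axis = c(10, 14))
  expect_equal(vapply(rs$blocks, `[[`, 0L, "slice"), 7:10)
  # five slices, tie towards the smaller index
  tum2 <- array(FALSE, d); tum2[8:12, 5:9, 5:9] <- TRUE
  rs2 <- place_muscle_rois(tum2, beam_axis = c(10, 14))
  expect_equal(vapply(rs2$blocks, `[[`, 0L, "slice"), 5:8)
  expect_error(place_muscle_rois(array(FALSE, d), c(1, 1)))
})

test_that("block placement matches the exhaustive brute-force search", {
  set.seed(23)
  for (i in 1:15) {
    sl <- matrix(FALSE, 24, 24)
    cx <- sample(6:18, 1); cy <- sample(6:18, 1)
    rx <- sample(2:6, 1); ry <- sample(2:6, 1)
    xs <- pmax(1, cx - rx):pmin(24, cx + rx)
    ys <- pmax(1, cy - ry):pmin(24, cy + ry)
    sl[xs, ys] <- TRUE
    beam <- c(runif(1, 1, 24), runif(1, 1, 24))
    got <- pdtvasc:::find_block(sl, beam, 5L, 1L)
    want <- brute_block(sl, beam, 5L, 1L)
    expect_equal(got$rows[1], want$i)
    expect_equal(got$cols[1], want$j)
  }
  # beam axis inside the tumor: block displaced to nearest feasible offset
  sl <- matrix(FALSE, 24, 24); sl[8:16, 8:16] <- TRUE
  got <- pdtvasc:::find_block(sl, c(12, 12), 5L, 1L)
  want <- brute_block(sl, c(12, 12), 5L, 1L)
  expect_equal(got$rows[1], want$i)
  expect_equal(got$cols[1], want$j)
  # tumor filling the slice: infeasible -> skipped with warning
  tum <- array(TRUE, c(10, 10, 6))
  w <- capture_warnings(rs <- place_muscle_rois(tum, c(5, 5)))
  expect_length(w, 4)
  expect_match(w, "skipped", all = TRUE)
  expect_length(rs$blocks, 0)
})

test_that("study summary aggregates per-compartment means correctly", {
  fx <- fixture_noiseless()
  fit <- pk_map(fx$conc)
  rois <- place_muscle_rois(fx$truth$tumor_mask, fx$truth$beam_axis)
  s <- summarize_study(fit, fx$conc, rois, fx$truth$tumor_mask)
  tr <- fx$truth
  # noiseless: summary matches truth-derived means below 1 %
  rim <- tr$tumor_mask & tr$ktrans_map > 0
  expect_equal(s$mean_ktrans_tumor_enhanced, mean(tr$ktrans_map[rim]),
               tolerance = 0.01)
  expect_equal(s$mean_ktrans_muscle, mean(tr$ktrans_map[rois$mask]),
               tolerance = 0.01)
  expect_equal(s$nonenhanced_fraction_tumor,
               100 * sum(tr$nonenhanced_core_mask) / sum(tr$tumor_mask))
  expect_equal(s$n_tumor, sum(tr$tumor_mask))
  df <- as.data.frame(s)
  expect_equal(nrow(df), 1)
  expect_true(all(c("nonenhanced_fraction_tumor", "mean_ktrans_muscle")
                  %in% names(df)))

  # mean over a union of disjoint ROIs equals the count-weighted mean
  a <- tr$tumor_mask & fit$fitted_mask
  b <- rois$mask & fit$fitted_mask
  stopifnot(sum(a & b) == 0)
  u <- mean(fit$ktrans[a | b])
  w <- (sum(a) * mean(fit$ktrans[a]) + sum(b) * mean(fit$ktrans[b])) /
    (sum(a) + sum(b))
  expect_equal(u, w, tolerance = 1e-12)
})

test_that("single-voxel ROI mean is the voxel value", {
  d <- c(6, 6, 6)
  fit <- structure(list(
    ktrans = array(NA_real_, d), ve = array(NA_real_, d),
    kep = array(NA_real_, d), rss = array(NA_real_, d),
    converged = array(NA, d), fitted_mask = array(FALSE, d)),
    class = "tofts_map")
  fit$ktrans[3, 3, 3] <- 0.2
  fit$converged[3, 3, 3] <- TRUE
  fit$fitted_mask[3, 3, 3] <- TRUE
  roi <- array(FALSE, d); roi[3, 3, 3] <- TRUE
  use <- fit$fitted_mask & fit$converged
  expect_equal(mean(fit$ktrans[use & roi]), 0.2)
})
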