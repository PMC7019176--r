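test_that("concentration definition: C = (R1(t) - R1,pre) / r1", {
  # constant-baseline voxel whose R1 jumps by exactly r1 => C = 1 mM
  p <- scan_protocol(n_frames = 40, injection_time = 60)
  times <- dce_times(p)
  r1pre <- 1 / 1.5
  m0 <- 1000
  r1t <- ifelse(times < p$injection_time, r1pre, r1pre + p$r1_relaxivity)
  sig <- array(0, c(1, 1, 1, length(times)))
  sig[1, 1, 1, ] <- spgr_signal(m0, 1 / r1t, p$fa_dce, p$tr_dce)
  dce <- dce_series(sig, times, p, array(TRUE, c(1, 1, 1)))
  r1map <- structure(list(
    r1_pre = array(r1pre, c(1, 1, 1)), t1 = array(1.5, c(1, 1, 1)),
    m0 = array(m0, c(1, 1, 1)), fit_residual = array(0, c(1, 1, 1)),
    valid = array(TRUE, c(1, 1, 1)), mask = array(TRUE, c(1, 1, 1)),
    protocol = p), class = "r1_map")
  cm <- signal_to_concentration(dce, r1map)
  post <- cm$conc[1, 1, 1, times >= p$injection_time]
  expect_equal(unname(post), rep(1, length(post)), tolerance = 1e-9)
  expect_true(cm$enhanced[1, 1, 1])

  # constant signal equal to baseline -> C(t) = 0, non-enhanced
  sig0 <- array(spgr_signal(m0, 1.5, p$fa_dce, p$tr_dce), c(1, 1, 1, length(times)))
  cm0 <- signal_to_concentration(dce_series(sig0, times, p, array(TRUE, c(1, 1, 1))), r1map)
  expect_true(all(abs(cm0$conc) < 1e-12))
  expect_false(cm0$enhanced[1, 1, 1])
})

test_that("noiseless phantom concentration curves match ground truth", {
  fx <- fixture_noiseless()
  tr <- fx$truth; cm <- fx$conc
  p <- fx$sim$dce$protocol
  times <- cm$times
  idx <- which(tr$tumor_mask & !tr$nonenhanced_core_mask)[c(1, 25, 50)]
  for (i in idx) {
    pos <- arrayInd(i, tr$dim)
    truth_curve <- tissue_concentration(times, tr$ktrans_map[i], tr$ve_map[i],
                                        t0 = p$injection_time)
    got <- cm$conc[pos[1], pos[2], pos[3], ]
    expect_lt(max(abs(got - truth_curve)), 1e-6)
  }
  # pre-injection frames are zero for noiseless input
  pre <- cm$conc[, , , cm$times < p$injection_time]
  expect_lt(max(abs(pre), na.rm = TRUE), 1e-12)
})

test_that("enhancement rule follows median-vs-2SD with the documented tie rule", {
  # SD = 0 tie rule: flat zero baseline, positive uptake -> enhanced
  tt <- 0:19
  expect_true(classify_enhancement(c(rep(0, 5), rep(0.5, 15)), tt, t0 = 5))
  expect_false(classify_enhancement(rep(0, 20), tt, t0 = 5))
  # direct rule: pre SD 0.05, post median 0.09 < 0.10 -> non-enhanced
  a <- 0.05 / sqrt(2)
  expect_false(classify_enhancement(c(-a, a, rep(0.09, 10)), 0:11, t0 = 2))
  # and 0.11 > 0.10 -> enhanced
  expect_true(classify_enhancement(c(-a, a, rep(0.11, 10)), 0:11, t0 = 2))
  expect_error(classify_enhancement(c(0, 1), c(0, 1), t0 = 0.5))
})

test_that("classifier agrees with the literal brute-force rule on random curves", {
  set.seed(5)
  tt <- seq(0, 120, by = 3)
  for (i in 1:200) {
    curve <- rnorm(length(tt), sd = runif(1, 0.01, 0.2)) +
      ifelse(tt >= 60, runif(1, -0.1, 0.5), 0)
    expect_identical(classify_enhancement(curve, tt, t0 = 60),
                     brute_classify(curve, tt, t0 = 60))
  }
})

test_that("AUC is a trapezoidal integral over the requested window", {
  fx <- fixture_noiseless()
  cm <- fx$conc
  auc <- auc_map(cm)
  expect_equal(auc[!cm$valid][1], NA_real_)
  core <- fx$truth$nonenhanced_core_mask
  expect_lt(max(abs(auc[core])), 1e-9)

  # fine-grid quadrature oracle on one enhancing voxel
  i <- which(fx$truth$ktrans_map > 0.2)[1]
  pos <- arrayInd(i, fx$truth$dim)
  p <- cm$protocol
  tfine <- seq(p$injection_time, max(cm$times), by = 0.01)
  cfine <- tissue_concentration(tfine, fx$truth$ktrans_map[i],
                                fx$truth$ve_map[i], t0 = p$injection_time)
  oracle <- sum((cfine[-1] + cfine[-length(cfine)]) / 2 * diff(tfine))
  expect_equal(auc[pos[1], pos[2], pos[3]], oracle, tolerance = 5e-3)

  # rectangle: constant 1 mM over a 60 s window
  cm2 <- cm
  cm2$conc[] <- 1
  w <- c(p$injection_time, p$injection_time + 63)
  sel <- cm$times >= w[1] & cm$times <= w[2]
  expect_equal(auc_map(cm2, w)[pos[1], pos[2], pos[3]],
               diff(range(cm$times[sel])))
  expect_error(auc_map(cm, c(0, 1)))
})
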