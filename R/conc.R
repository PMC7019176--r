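#' Classify a concentration curve as enhanced or non-enhanced
#'
#' A voxel is non-enhanced when the median of the concentration curve at and
#' after the injection time is smaller than twice the standard deviation of
#' the pre-injection frames; otherwise it is enhanced. "Before injection"
#' means frames with `t < t0`, "after" means `t >= t0`; the few seconds of
#' injection duration are ignored. The baseline SD is the sample (n-1) SD by
#' default. Degenerate baseline (SD exactly 0, e.g. noiseless data): the
#' voxel is non-enhanced iff the post-injection median is `<= 0`, judged
#' with a 1e-12 mM absolute tolerance so that floating-point residuals of
#' the signal inversion cannot flip the branch. Missing
#' frames (`NA`) are excluded from both the median and the SD.
#'
#' @param conc_curve Concentration time series (mM).
#' @param times Frame times (seconds), same length.
#' @param t0 Injection time (seconds).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return `TRUE` if enhanced, `FALSE` if non-enhanced.
#' @export
classify_enhancement <- function(conc_curve, times, t0,
                                 sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(conc_curve) == length(times))
  pre <- conc_curve[times < t0]
  post <- conc_curve[times >= t0]
  pre <- pre[is.finite(pre)]
  post <- post[is.finite(post)]
  if (length(pre) < 2 || length(post) < 1)
    stop("need >= 2 pre-injection and >= 1 post-injection frames")
  s <- stats::sd(pre)
  if (sd_type == "population") s <- s * sqrt((length(pre) - 1) / length(pre))
  m <- stats::median(post)
  if (s == 0) return(!(m <= 1e-12))
  !(m < 2 * s)
}

#' Convert a DCE signal series to contrast-agent concentration
#'
#' Per masked voxel with a valid pre-contrast R1: an effective M0 is
#' calibrated from the mean pre-injection signal and \eqn{R_{1,pre}} through
#' the SPGR equation (using the mean of all pre-injection frames maximizes
#' baseline SNR), \eqn{R_1(t)} is obtained frame-by-frame with
#' [invert_spgr()], and \eqn{C(t) = (R_1(t) - R_{1,pre}) / r_1} with the
#' protocol's relaxivity. Frames whose signal falls outside the SPGR
#' invertibility range are carried as `NA` and excluded from downstream
#' medians, SDs and integrals. Voxels with an invalid R1 fit are excluded
#' entirely. Each voxel is then classified with [classify_enhancement()].
#'
#' @param dce A [dce_series()].
#' @param r1map An `r1_map` from [fit_t1_vfa()].
#' @param sd_type Baseline SD convention, see [classify_enhancement()].
#' @return Object of class `conc_maps`: 4-D arrays `conc` (mM) and `r1_t`
#'   (s^-1); 3-D logical `enhanced` (NA outside mask/valid); `valid`;
#'   `times`; `baseline_frames` (indices with `t < t0`); `protocol`.
#' @export
signal_to_concentration <- function(dce, r1map,
                                    sd_type = c("sample", "population")) {
  stopifnot(inherits(dce, "dce_series"), inherits(r1map, "r1_map"))
  sd_type <- match.arg(sd_type)
  p <- dce$protocol
  d <- dim(dce$signal)[1:3]
  stopifnot(identical(d, dim(r1map$valid)))
  times <- dce$times
  base <- which(times < p$injection_time)
  if (length(base) < 2) stop("need >= 2 pre-injection frames")

  valid <- dce$mask & r1map$valid
  idx <- which(valid)
  nt <- length(times)
  sig <- matrix(dce$signal, prod(d))[idx, , drop = FALSE]
  r1pre <- r1map$r1_pre[idx]

  # effective M0 from baseline mean and known R1,pre
  a <- p$fa_dce * pi / 180
  e1 <- exp(-p$tr_dce * r1pre)
  sbase <- rowMeans(sig[, base, drop = FALSE])
  m0_eff <- sbase * (1 - e1 * cos(a)) / (sin(a) * (1 - e1))

  r1t <- invert_spgr(sig, m0_eff, p$fa_dce, p$tr_dce)  # recycles m0 by row
  # Reference the dynamic R1 against the mean of the inverted baseline
  # frames. By construction of m0_eff this equals R1,pre up to floating
  # point, but using the measured reference keeps C(t) exactly zero on a
  # flat baseline instead of leaving +/- 1 ulp residuals whose sign would
  # flip the degenerate (SD = 0) branch of the enhancement rule.
  r1ref <- rowMeans(r1t[, base, drop = FALSE], na.rm = TRUE)
  bad_ref <- !is.finite(r1ref)
  r1ref[bad_ref] <- r1pre[bad_ref]
  conc <- (r1t - r1ref) / p$r1_relaxivity

  enh_vec <- vapply(seq_len(nrow(conc)), function(i) {
    classify_enhancement(conc[i, ], times, p$injection_time, sd_type)
  }, logical(1))

  conc4 <- array(NA_real_, c(d, nt))
  r1t4 <- array(NA_real_, c(d, nt))
  cf <- matrix(conc4, prod(d), nt); cf[idx, ] <- conc
  rf <- matrix(r1t4, prod(d), nt); rf[idx, ] <- r1t
  enh <- array(NA, d); enh[idx] <- enh_vec
  structure(list(
    conc = array(cf, c(d, nt)), r1_t = array(rf, c(d, nt)),
    enhanced = enh, valid = valid, times = times,
    baseline_frames = base, protocol = p
  ), class = "conc_maps")
}

#' @export
print.conc_maps <- function(x, ...) {
  n <- sum(x$valid)
  cat(sprintf("Concentration maps: %d analysed voxels, %d frames\n",
              n, length(x$times)))
  cat(sprintf("  enhanced %d, non-enhanced %d\n",
              sum(x$enhanced, na.rm = TRUE),
              sum(!x$enhanced, na.rm = TRUE)))
  invisible(x)
}

# Trapezoidal integral along rows of a matrix with possibly missing values:
# missing frames are dropped per voxel.
trapz_rows <- function(y, t) {
  out <- numeric(nrow(y))
  dt <- diff(t)
  mid <- (y[, -1, drop = FALSE] + y[, -ncol(y), drop = FALSE]) / 2
  ok <- is.finite(mid)
  if (all(ok)) return(as.numeric(mid %*% dt))
  for (i in seq_len(nrow(y))) {
    yi <- y[i, ]
    f <- which(is.finite(yi))
    if (length(f) < 2) { out[i] <- NA_real_; next }
    out[i] <- sum(diff(t[f]) * (yi[f][-1] + yi[f][-length(f)]) / 2)
  }
  out
}

#' Area under the concentration curve
#'
#' Trapezoidal integral of C(t) per voxel over a time window, by default from
#' the injection time to the end of the scan.
#'
#' @param conc A `conc_maps` object.
#' @param window Length-2 numeric `c(start, end)` in seconds, or `NULL` for
#'   injection-to-end.
#' @return 3-D array of AUC in mM*s (`NA` outside analysed voxels).
#' @export
auc_map <- function(conc, window = NULL) {
  stopifnot(inherits(conc, "conc_maps"))
  if (is.null(window))
    window <- c(conc$protocol$injection_time, max(conc$times))
  stopifnot(length(window) == 2, window[1] < window[2])
  sel <- conc$times >= window[1] & conc$times <= window[2]
  if (sum(sel) < 2) stop("AUC window contains fewer than 2 frames")
  d <- dim(conc$enhanced)
  idx <- which(conc$valid)
  nt <- dim(conc$conc)[4]
  cm <- matrix(conc$conc, prod(d), nt)[idx, sel, drop = FALSE]
  v <- trapz_rows(cm, conc$times[sel])
  out <- array(NA_real_, d)
  out[idx] <- v
  out
}
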