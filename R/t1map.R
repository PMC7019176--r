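#' Invert the spoiled gradient-echo equation for R1
#'
#' Solves the SPGR steady-state equation for the relaxation rate:
#' \eqn{E_1 = (M_0 \sin\alpha - S) / (M_0 \sin\alpha - S\cos\alpha)},
#' \eqn{R_1 = -\ln E_1 / TR}. The exact algebraic inverse of
#' [spgr_signal()]. Signals outside the invertibility range
#' \eqn{0 < S < M_0\sin\alpha/(1-\cos\alpha)} (i.e. `E1` outside (0, 1),
#' including `S = 0` where `E1 = 1`) are flagged by returning `NA`, never by
#' raising an error, so single bad frames can be carried as missing.
#'
#' @param signal Measured signal (vectorized).
#' @param m0 Equilibrium signal.
#' @param alpha Flip angle (degrees).
#' @param tr Repetition time (seconds).
#' @return R1 in s^-1; `NA` where the signal is not invertible.
#' @export
invert_spgr <- function(signal, m0, alpha, tr) {
  stopifnot(all(alpha > 0), all(alpha < 90), all(tr > 0))
  a <- alpha * pi / 180
  num <- m0 * sin(a) - signal
  den <- m0 * sin(a) - signal * cos(a)
  e1 <- num / den
  r1 <- rep(NA_real_, length(e1))
  ok <- is.finite(e1) & e1 > 0 & e1 < 1
  r1[ok] <- -log(e1[ok]) / tr
  if (!is.null(dim(signal))) dim(r1) <- dim(signal)
  r1
}

# Linearized VFA estimate: S/sin(a) = E1 * S/tan(a) + M0 (1 - E1).
# sig: nvox x nangles matrix. Returns list(e1, m0, valid).
vfa_linear_fit <- function(sig, angles) {
  a <- angles * pi / 180
  y <- sweep(sig, 2, sin(a), `/`)
  x <- sweep(sig, 2, tan(a), `/`)
  n <- ncol(sig)
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x * x); sxy <- rowSums(x * y)
  den <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / den
  icpt <- (sy - slope * sx) / n
  valid <- is.finite(slope) & slope > 0 & slope < 1 & icpt > 0
  m0 <- icpt / (1 - slope)
  list(e1 = slope, m0 = m0, valid = valid)
}

#' Voxelwise T1/M0 estimation from a variable-flip-angle series
#'
#' Two-stage fit of the SPGR signal model at each masked voxel: the
#' linearized DESPOT1 form \eqn{S/\sin\alpha = E_1 (S/\tan\alpha) +
#' M_0(1-E_1)} provides the initial estimate, followed by bounded nonlinear
#' least-squares refinement (vectorized Levenberg-Marquardt on (M0, T1))
#' since the linear fit is noise-biased. T1 is constrained to
#' `t1_bounds` (default 0.05-10 s, excluding non-tissue solutions). Voxels
#' with all-zero signal or a non-physical linearized slope (`E1` outside
#' (0, 1)) are flagged `valid = FALSE` and excluded downstream - never
#' carried as zeros.
#'
#' @param series A [vfa_series()].
#' @param t1_bounds Lower/upper T1 bounds (seconds).
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return Object of class `r1_map` with 3-D arrays `r1_pre` (s^-1), `t1`
#'   (s), `m0`, `fit_residual` (root-mean-square residual, signal units) and
#'   logical `valid`; plus the input `mask` and `protocol`.
#' @export
fit_t1_vfa <- function(series, t1_bounds = c(0.05, 10), max_iter = 50L) {
  stopifnot(inherits(series, "vfa_series"), sum(series$mask) > 0)
  d <- dim(series$signal)[1:3]
  idx <- which(series$mask)
  sig <- matrix(series$signal, prod(d))[idx, , drop = FALSE]
  angles <- series$angles
  tr <- series$protocol$tr_vfa
  nonzero <- rowSums(abs(sig)) > 0

  lin <- vfa_linear_fit(sig, angles)
  valid <- lin$valid & nonzero
  t1 <- pmin(t1_bounds[2], pmax(t1_bounds[1], -tr / log(pmax(lin$e1, 1e-12))))
  m0 <- lin$m0
  t1[!valid] <- NA_real_; m0[!valid] <- NA_real_

  ref <- lm_refine_spgr(sig[valid, , drop = FALSE], angles, tr,
                        m0[valid], t1[valid], t1_bounds, max_iter)
  m0[valid] <- ref$m0
  t1[valid] <- ref$t1
  rms <- rep(NA_real_, length(idx))
  rms[valid] <- ref$rms

  to_arr <- function(v, fill = NA_real_) {
    a <- array(fill, d); a[idx] <- v; a
  }
  va <- array(FALSE, d); va[idx] <- valid
  structure(list(
    r1_pre = to_arr(1 / t1), t1 = to_arr(t1), m0 = to_arr(m0),
    fit_residual = to_arr(rms), valid = va,
    mask = series$mask, protocol = series$protocol
  ), class = "r1_map")
}

#' @export
print.r1_map <- function(x, ...) {
  v <- x$t1[x$valid]
  cat(sprintf("VFA T1 map: %d valid voxels (of %d masked)\n",
              sum(x$valid), sum(x$mask)))
  if (length(v))
    cat(sprintf("  T1 median %.3f s [%.3f, %.3f]\n",
                stats::median(v), min(v), max(v)))
  invisible(x)
}

# Vectorized Levenberg-Marquardt refinement of (m0, t1) per voxel.
lm_refine_spgr <- function(sig, angles, tr, m0, t1, t1_bounds, max_iter) {
  nv <- nrow(sig)
  if (nv == 0) return(list(m0 = m0, t1 = t1, rms = numeric(0)))
  a <- angles * pi / 180
  sa <- sin(a); ca <- cos(a)
  model <- function(m0, t1) {
    e1 <- exp(-tr / t1)
    s <- outer(m0, sa) * (1 - e1) / (1 - outer(e1, ca))
    s
  }
  rss_of <- function(m0, t1) rowSums((sig - model(m0, t1))^2)
  lambda <- rep(1e-3, nv)
  rss <- rss_of(m0, t1)
  for (it in seq_len(max_iter)) {
    e1 <- exp(-tr / t1)
    de1 <- e1 * tr / t1^2                      # dE1/dT1
    den <- 1 - outer(e1, ca)
    f <- outer(m0, sa) * (1 - e1) / den
    j1 <- f / m0                               # dS/dM0
    j2 <- outer(m0 * de1, sa * (ca - 1)) / den^2   # dS/dT1
    r <- sig - f
    g1 <- rowSums(j1 * r); g2 <- rowSums(j2 * r)
    h11 <- rowSums(j1 * j1); h22 <- rowSums(j2 * j2); h12 <- rowSums(j1 * j2)
    d11 <- h11 * (1 + lambda); d22 <- h22 * (1 + lambda)
    det <- d11 * d22 - h12^2
    dm0 <- (d22 * g1 - h12 * g2) / det
    dt1 <- (d11 * g2 - h12 * g1) / det
    bad <- !is.finite(dm0) | !is.finite(dt1)
    dm0[bad] <- 0; dt1[bad] <- 0
    m0n <- m0 + dm0
    t1n <- pmin(t1_bounds[2], pmax(t1_bounds[1], t1 + dt1))
    m0n <- pmax(m0n, 1e-12)
    rssn <- rss_of(m0n, t1n)
    acc <- is.finite(rssn) & rssn <= rss
    m0[acc] <- m0n[acc]; t1[acc] <- t1n[acc]
    lambda[acc] <- pmax(lambda[acc] / 3, 1e-10)
    lambda[!acc] <- pmin(lambda[!acc] * 8, 1e8)
    conv <- if (any(acc))
      max(abs(rss[acc] - rssn[acc]) / (rssn[acc] + 1e-30)) else 0
    rss[acc] <- rssn[acc]
    if (it > 5 && conv < 1e-13) break
  }
  list(m0 = m0, t1 = t1, rms = sqrt(rss / length(angles)))
}
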