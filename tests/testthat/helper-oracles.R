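# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form code paths: the convolution oracle integrates the
# model ODE kernel numerically, the classifier oracle restates the rule
# literally, and the rank oracle goes through rank() + Pearson cor().

# Tofts tissue curve by cumulative-trapezoid discrete convolution of the
# bi-exponential AIF with exp(-kep * t) at step dt, evaluated at t_out.
disc_conv_tofts <- function(t_out, ktrans, ve, aif = aif_params(),
                            t0 = 120, dt = 0.01) {
  kt_s <- ktrans / 60
  kep <- kt_s / ve
  tmax <- max(t_out)
  tau <- seq(t0, tmax, by = dt)
  cp <- aif$a1 * exp(-(tau - t0) / aif$tau1) +
    aif$a2 * exp(-(tau - t0) / aif$tau2)
  # C(t) = kt * exp(-kep t) * int_0^t cp(tau) exp(kep tau) dtau
  g <- cp * exp(kep * (tau - t0))
  cum <- c(0, cumsum((g[-1] + g[-length(g)]) / 2 * dt))
  ct <- kt_s * exp(-kep * (tau - t0)) * cum
  out <- numeric(length(t_out))
  sel <- t_out >= t0
  out[sel] <- stats::approx(tau, ct, xout = t_out[sel], rule = 2)$y
  out
}

# Literal restatement of the enhancement rule: non-enhanced when the median
# of the curve at/after injection is smaller than twice the SD before it.
brute_classify <- function(curve, times, t0) {
  pre <- curve[times < t0]
  post <- curve[times >= t0]
  !(stats::median(post) < 2 * stats::sd(pre))
}

# Spearman via explicit average ranks then Pearson correlation.
brute_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# Exhaustive candidate-block search for the muscle ROI placement.
brute_block <- function(sl, beam_axis, block = 5L, spacing = 1L) {
  nr <- nrow(sl); nc <- ncol(sl)
  best <- NULL
  for (i in seq_len(nr - block + 1)) {
    for (j in seq_len(nc - block + 1)) {
      rr <- max(1, i - spacing):min(nr, i + block - 1 + spacing)
      cc <- max(1, j - spacing):min(nc, j + block - 1 + spacing)
      if (any(sl[rr, cc])) next
      ctr <- c(i + (block - 1) / 2, j + (block - 1) / 2)
      d2 <- sum((ctr - beam_axis)^2)
      if (is.null(best) || d2 < best$d2 - 1e-12 ||
          (abs(d2 - best$d2) <= 1e-12 &&
           (i < best$i || (i == best$i && j < best$j))))
        best <- list(i = i, j = j, d2 = d2)
    }
  }
  best
}
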