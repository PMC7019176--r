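# Precompute the AIF-dependent pieces of the Tofts model on a time grid so
# repeated objective evaluations only pay for one exp() per call.
tofts_basis <- function(times, aif, t0) {
  td <- times - t0
  on <- td >= 0
  td <- td[on]
  list(td = td, on = on, n = length(times),
       a = c(aif$a1, aif$a2), itau = 1 / c(aif$tau1, aif$tau2),
       eatau = cbind(exp(-td / aif$tau1), exp(-td / aif$tau2)))
}

# Model curve on the post-injection part only, for ktrans [min^-1], ve.
tofts_eval_post <- function(basis, ktrans, ve, tol = 1e-8) {
  kt_s <- ktrans / 60
  kep <- kt_s / ve
  ek <- exp(-kep * basis$td)
  acc <- 0
  for (i in 1:2) {
    d <- kep - basis$itau[i]
    acc <- acc + if (abs(d) < tol) {
      basis$a[i] * basis$td * ek
    } else {
      basis$a[i] * (basis$eatau[, i] - ek) / d
    }
  }
  kt_s * acc
}

# Curve plus analytic partials wrt ktrans (min^-1) and ve, post frames only.
tofts_eval_post_grad <- function(basis, ktrans, ve, tol = 1e-8) {
  kt_s <- ktrans / 60
  kep <- kt_s / ve
  td <- basis$td
  ek <- exp(-kep * td)
  f <- 0; fp <- 0
  for (i in 1:2) {
    d <- kep - basis$itau[i]
    if (abs(d) < tol) {
      f <- f + basis$a[i] * td * ek
      fp <- fp - basis$a[i] * td^2 * ek
    } else {
      fi <- (basis$eatau[, i] - ek) / d
      f <- f + basis$a[i] * fi
      fp <- fp + basis$a[i] * (td * ek * d - (basis$eatau[, i] - ek)) / d^2
    }
  }
  list(c = kt_s * f,
       dkt = (f + kep * fp) / 60,    # d/d ktrans[min^-1]
       dve = -kep^2 * fp)
}

#' Fit the standard Tofts-Kermode model to one concentration curve
#'
#' Bounded nonlinear least squares of the closed-form Tofts-Kermode tissue
#' curve (see [tissue_concentration()]) against a measured concentration
#' curve, under a fixed bi-exponential AIF. The residual-sum-of-squares
#' surface is multimodal at low SNR, so the optimizer (`L-BFGS-B`) is started
#' from a 3 x 3 grid, Ktrans in {0.01, 0.1, 0.5} min^-1 by ve in
#' {0.1, 0.3, 0.6}, and the best-RSS solution wins; RSS ties (relative
#' difference < 1e-9) are broken towards the smallest Ktrans. Bounds:
#' Ktrans in [0, 5] min^-1, ve in [1e-3, 1]. `kep = ktrans / ve` is reported
#' as a derived quantity, never independently fitted. This is the standard
#' (two-parameter) model - no plasma-volume term.
#'
#' @param conc_curve Tissue concentration (mM) per frame; `NA` frames are
#'   dropped.
#' @param times Frame times (seconds).
#' @param aif An [aif_params()].
#' @param t0 Injection time (seconds).
#' @param bounds_ktrans,bounds_ve Box constraints for the two parameters.
#' @param starts Optional data frame with columns `ktrans`, `ve` overriding
#'   the default multi-start grid.
#' @return Object of class `tofts_fit` with elements `ktrans` (min^-1), `ve`,
#'   `kep` (min^-1), `rss` (mM^2), `converged`, `fitted`, plus the data;
#'   supports `print()`, `coef()`, `predict()`, `residuals()`, `plot()`.
#' @examples
#' tt <- seq(0, 420, by = 3.5)
#' cv <- tissue_concentration(tt, 0.25, 0.4, t0 = 120)
#' fit <- fit_tofts(cv, tt, t0 = 120)
#' coef(fit)
#' @export
fit_tofts <- function(conc_curve, times, aif = aif_params(), t0 = 120,
                      bounds_ktrans = c(0, 5), bounds_ve = c(1e-3, 1),
                      starts = NULL) {
  stopifnot(length(conc_curve) == length(times), inherits(aif, "aif_params"))
  if (sum(times >= t0 & is.finite(conc_curve)) < 10)
    stop("need >= 10 finite post-injection frames")
  if (is.null(starts))
    starts <- expand.grid(ktrans = c(0.01, 0.1, 0.5), ve = c(0.1, 0.3, 0.6))
  basis <- tofts_basis(times, aif, t0)
  ans <- tofts_fit_engine(conc_curve, basis, starts, bounds_ktrans, bounds_ve)
  fitted <- numeric(length(times))
  fitted[basis$on] <- tofts_eval_post(basis, ans$ktrans, ans$ve)
  structure(list(
    ktrans = ans$ktrans, ve = ans$ve, kep = ans$ktrans / ans$ve,
    rss = ans$rss, converged = ans$converged,
    fitted = fitted, conc = conc_curve, times = times, aif = aif, t0 = t0
  ), class = "tofts_fit")
}

# Core engine shared by fit_tofts() and pk_map(): bounded least squares with
# analytic gradients, run from every start on the grid; the best-RSS winner
# (ties towards smaller Ktrans) is then polished at tight tolerance.
tofts_fit_engine <- function(curve, basis, starts, bk, bv) {
  ok <- is.finite(curve)
  y <- curve[ok]
  sub <- ok[basis$on]             # which post-injection frames are retained
  y_post <- curve[basis$on][sub]
  rss_pre <- sum(y^2) - sum(y_post^2)   # pre-injection model is zero
  obj <- function(par) {
    m <- tofts_eval_post(basis, par[1], par[2])[sub]
    rss_pre + sum((y_post - m)^2)
  }
  grad <- function(par) {
    g <- tofts_eval_post_grad(basis, par[1], par[2])
    r <- y_post - g$c[sub]
    -2 * c(sum(r * g$dkt[sub]), sum(r * g$dve[sub]))
  }
  run <- function(par, factr) {
    stats::optim(par, obj, grad, method = "L-BFGS-B",
                 lower = c(bk[1], bv[1]), upper = c(bk[2], bv[2]),
                 control = list(factr = factr, maxit = 200))
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- run(c(starts$ktrans[s], starts$ve[s]), 1e7)
    cand <- list(par = o$par, rss = o$value)
    if (is.null(best) ||
        cand$rss < best$rss * (1 - 1e-9) ||
        (abs(cand$rss - best$rss) <= 1e-9 * max(best$rss, 1e-300) &&
         cand$par[1] < best$par[1]))
      best <- cand
  }
  o <- run(best$par, 10)
  if (o$value > best$rss) o <- list(par = best$par, value = best$rss,
                                    convergence = 0L)
  list(ktrans = o$par[1], ve = o$par[2], rss = o$value,
       converged = o$convergence == 0)
}

#' @export
print.tofts_fit <- function(x, ...) {
  cat("Tofts-Kermode fit\n")
  cat(sprintf("  Ktrans = %.4g min^-1, ve = %.4g, kep = %.4g min^-1\n",
              x$ktrans, x$ve, x$kep))
  cat(sprintf("  RSS = %.4g mM^2 over %d frames; converged: %s\n",
              x$rss, sum(is.finite(x$conc)), x$converged))
  invisible(x)
}

#' @export
coef.tofts_fit <- function(object, ...) {
  c(ktrans = object$ktrans, ve = object$ve, kep = object$kep)
}

#' Predict the fitted tissue concentration curve
#'
#' @param object A `tofts_fit`.
#' @param times Optional new time grid (seconds); defaults to the fitted one.
#' @param ... Unused.
#' @return Concentration (mM) at `times`.
#' @export
predict.tofts_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  tissue_concentration(times, object$ktrans, object$ve, object$aif,
                       object$t0)
}

#' @export
residuals.tofts_fit <- function(object, ...) object$conc - object$fitted

#' @export
plot.tofts_fit <- function(x, ...) {
  graphics::plot(x$times / 60, x$conc, pch = 20, cex = 0.5,
                 xlab = "time (min)", ylab = "C(t) (mM)", ...)
  graphics::lines(x$times / 60, x$fitted, col = 2, lwd = 2)
  graphics::abline(v = x$t0 / 60, lty = 3)
  invisible(x)
}

#' Voxelwise Tofts-Kermode parameter maps
#'
#' Applies [fit_tofts()] to every analysed voxel that is classified as
#' enhanced; non-enhanced voxels carry `NA` (undefined, deliberately distinct
#' from Ktrans = 0) in all output maps, matching the convention of analysing
#' enhanced pixels only.
#'
#' @param conc A `conc_maps` object from [signal_to_concentration()].
#' @param aif An [aif_params()].
#' @param ... Passed to the fitting engine ([fit_tofts()] bounds/starts).
#' @return Object of class `tofts_map`: 3-D arrays `ktrans`, `ve`, `kep`
#'   (min^-1), `rss`, logical `converged` and `fitted_mask`.
#' @export
pk_map <- function(conc, aif = aif_params(), ...) {
  stopifnot(inherits(conc, "conc_maps"))
  d <- dim(conc$enhanced)
  fit_vox <- conc$valid & !is.na(conc$enhanced) & conc$enhanced
  idx <- which(fit_vox)
  kt <- array(NA_real_, d); ve <- array(NA_real_, d)
  rss <- array(NA_real_, d); cv <- array(NA, d)
  if (length(idx) == 0) {
    warning("no enhanced voxels to fit; returning empty maps")
    return(structure(list(ktrans = kt, ve = ve, kep = kt, rss = rss,
                          converged = cv, fitted_mask = fit_vox),
                     class = "tofts_map"))
  }
  dots <- list(...)
  starts <- dots$starts %||%
    expand.grid(ktrans = c(0.01, 0.1, 0.5), ve = c(0.1, 0.3, 0.6))
  bk <- dots$bounds_ktrans %||% c(0, 5)
  bv <- dots$bounds_ve %||% c(1e-3, 1)
  nt <- dim(conc$conc)[4]
  cm <- matrix(conc$conc, prod(d), nt)[idx, , drop = FALSE]
  basis <- tofts_basis(conc$times, aif, conc$protocol$injection_time)
  for (i in seq_along(idx)) {
    ans <- tofts_fit_engine(cm[i, ], basis, starts, bk, bv)
    kt[idx[i]] <- ans$ktrans; ve[idx[i]] <- ans$ve
    rss[idx[i]] <- ans$rss; cv[idx[i]] <- ans$converged
  }
  structure(list(ktrans = kt, ve = ve, kep = kt / ve, rss = rss,
                 converged = cv, fitted_mask = fit_vox),
            class = "tofts_map")
}

#' @export
print.tofts_map <- function(x, ...) {
  n <- sum(x$fitted_mask)
  cat(sprintf("Tofts-Kermode maps: %d fitted voxels (%d converged)\n",
              n, sum(x$converged, na.rm = TRUE)))
  if (n > 0)
    cat(sprintf("  median Ktrans %.3g min^-1, median ve %.3g\n",
                stats::median(x$ktrans, na.rm = TRUE),
                stats::median(x$ve, na.rm = TRUE)))
  invisible(x)
}
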