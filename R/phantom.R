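#' Plasma concentration of the bi-exponential arterial input function
#'
#' Evaluates \eqn{C_p(t)}: zero before the injection time `t0`, and
#' \eqn{\sum_i A_i \exp(-(t - t_0)/\tau_i)} at and after it (continuous from
#' the right at `t0`).
#'
#' @param t Times (seconds), `t >= 0`. Vectorized.
#' @param aif An [aif_params()].
#' @param t0 Injection time (seconds).
#' @return Plasma concentration in mM, same length as `t`.
#' @examples
#' aif_concentration(120, aif_params(), t0 = 120)  # A1 + A2 = 6.63 mM
#' @export
aif_concentration <- function(t, aif = aif_params(), t0 = 120) {
  stopifnot(inherits(aif, "aif_params"), all(t >= 0), t0 >= 0)
  td <- t - t0
  out <- numeric(length(t))
  on <- td >= 0
  out[on] <- aif$a1 * exp(-td[on] / aif$tau1) +
    aif$a2 * exp(-td[on] / aif$tau2)
  out
}

#' Tissue concentration under the Tofts-Kermode model
#'
#' Closed-form solution of the standard (two-parameter) Tofts-Kermode model
#' driven by a bi-exponential AIF:
#' \deqn{C_t(t) = K^{trans} \sum_i A_i
#'   \frac{e^{-(t-t_0)/\tau_i} - e^{-k_{ep}(t-t_0)}}{k_{ep} - 1/\tau_i},}
#' with \eqn{k_{ep} = K^{trans}/v_e}. When \eqn{|k_{ep} - 1/\tau_i|} falls
#' below `tol` the analytic limit
#' \eqn{A_i K^{trans} (t-t_0) e^{-k_{ep}(t-t_0)}} replaces the term, avoiding
#' catastrophic cancellation at the degenerate point. Ktrans is given in the
#' field convention min^-1 and converted internally to s^-1 so that times and
#' AIF time constants stay in seconds.
#'
#' @param t Times (seconds), vectorized.
#' @param ktrans Transfer constant (min^-1), `>= 0`.
#' @param ve Extravascular extracellular volume fraction, in (0, 1].
#' @param aif An [aif_params()].
#' @param t0 Injection time (seconds).
#' @param tol Degeneracy switch tolerance on `|kep - 1/tau_i|` (s^-1).
#' @return Tissue concentration in mM, same length as `t`.
#' @export
tissue_concentration <- function(t, ktrans, ve, aif = aif_params(),
                                 t0 = 120, tol = 1e-8) {
  stopifnot(inherits(aif, "aif_params"), ktrans >= 0)
  if (ktrans > 0 && (ve <= 0 || ve > 1))
    stop("ve must lie in (0, 1] when ktrans > 0")
  out <- numeric(length(t))
  if (ktrans == 0) return(out)
  kt_s <- ktrans / 60
  kep_s <- kt_s / ve
  td <- t - t0
  on <- td >= 0
  td <- td[on]
  ek <- exp(-kep_s * td)
  acc <- numeric(length(td))
  for (i in 1:2) {
    a <- c(aif$a1, aif$a2)[i]
    tau <- c(aif$tau1, aif$tau2)[i]
    d <- kep_s - 1 / tau
    acc <- acc + if (abs(d) < tol) {
      a * td * ek
    } else {
      a * (exp(-td / tau) - ek) / d
    }
  }
  out[on] <- kt_s * acc
  out
}

#' Spoiled gradient-echo steady-state signal
#'
#' \deqn{S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha}, \quad
#'   E_1 = e^{-TR/T_1}.}
#' All arguments are vectorized and recycled.
#'
#' @param m0 Equilibrium signal (signal units).
#' @param t1 Longitudinal relaxation time (seconds), `> 0`.
#' @param alpha Flip angle (degrees), in (0, 90).
#' @param tr Repetition time (seconds), `> 0`.
#' @return Signal in the same units as `m0`.
#' @export
spgr_signal <- function(m0, t1, alpha, tr) {
  stopifnot(all(t1 > 0), all(tr > 0), all(alpha > 0), all(alpha < 90))
  a <- alpha * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Synthetic ground-truth tissue maps
#'
#' Builds the digital phantom used throughout the package for validation by
#' parameter recovery: an ellipsoidal tumor with a concentric non-enhancing
#' core (Ktrans = 0, emulating vascular shutdown) and a rectangular muscle
#' slab, embedded in a `dim[1] x dim[2] x dim[3]` grid. Within the enhancing
#' tumor rim, Ktrans varies smoothly over [0.01, 1] min^-1 and ve over
#' [0.1, 0.6] (deterministic smooth spatial fields); muscle has uniform
#' low-level perfusion. T1 values are typical 7 T tissue values.
#'
#' @param dim Grid dimensions (voxels), default `c(64, 64, 17)`.
#' @param voxel_size Voxel size in mm, default `c(0.3125, 0.3125, 1.29)`.
#' @param tumor_center,tumor_semiaxes Ellipsoid center and semi-axes (voxels).
#' @param core_fraction Volume fraction of the tumor occupied by the
#'   non-enhancing core (concentric ellipsoid), default 0.3.
#' @param muscle_box List with integer ranges `x`, `y`, `z` for the muscle
#'   slab, or `NULL` for the default slab below the tumor.
#' @param t1_tumor,t1_muscle,t1_core T1 values (seconds).
#' @param m0 Equilibrium signal in tissue (signal units).
#' @param ktrans_range,ve_range Ranges spanned by the rim Ktrans (min^-1) and
#'   ve fields.
#' @param ktrans_muscle,ve_muscle Muscle pharmacokinetic parameters.
#' @return An object of class `phantom_truth` with fields `t1_map`, `m0_map`,
#'   `ktrans_map`, `ve_map`, `tumor_mask`, `nonenhanced_core_mask`,
#'   `muscle_mask`, `tissue_mask`, `dim`, `voxel_size`, `beam_axis`.
#' @export
phantom_truth <- function(dim = c(64, 64, 17),
                          voxel_size = c(0.3125, 0.3125, 1.29),
                          tumor_center = NULL,
                          tumor_semiaxes = NULL,
                          core_fraction = 0.3,
                          muscle_box = NULL,
                          t1_tumor = 1.9, t1_muscle = 1.5, t1_core = 2.2,
                          m0 = 1000,
                          ktrans_range = c(0.01, 1), ve_range = c(0.1, 0.6),
                          ktrans_muscle = 0.08, ve_muscle = 0.15) {
  stopifnot(length(dim) == 3, all(dim[1:2] >= 16), dim[3] >= 4,
            core_fraction >= 0,
            core_fraction < 1, all(ktrans_range > 0), all(ve_range > 0),
            all(ve_range <= 1))
  dim <- as.integer(dim)
  if (is.null(tumor_center)) tumor_center <- c(dim[1] / 2, dim[2] / 2 - 4, (dim[3] + 1) / 2)
  if (is.null(tumor_semiaxes))
    tumor_semiaxes <- pmax(2, c(dim[1] * 0.18, dim[2] * 0.16, dim[3] * 0.32))

  ax <- (seq_len(dim[1]) - tumor_center[1]) / tumor_semiaxes[1]
  ay <- (seq_len(dim[2]) - tumor_center[2]) / tumor_semiaxes[2]
  az <- (seq_len(dim[3]) - tumor_center[3]) / tumor_semiaxes[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  tumor <- r2 <= 1
  core <- r2 <= core_fraction^(2 / 3)   # concentric ellipsoid, volume ratio = core_fraction

  if (is.null(muscle_box)) {
    # muscle slab under the tumor along the light-beam direction, with a
    # small gap so 5x5 reference blocks keep >= 1 px spacing to the tumor
    y0 <- min(dim[2] - 7, ceiling(tumor_center[2] + tumor_semiaxes[2]) + 3)
    muscle_box <- list(x = seq(max(1, round(dim[1] * 0.25)),
                               min(dim[1], round(dim[1] * 0.75))),
                       y = seq(y0, min(dim[2], y0 + 7)),
                       z = seq_len(dim[3]))
  }
  muscle <- array(FALSE, dim)
  muscle[muscle_box$x, muscle_box$y, muscle_box$z] <- TRUE
  muscle <- muscle & !tumor

  # smooth deterministic parameter fields across the grid (low spatial frequency)
  gx <- matrix(seq_len(dim[1]) / dim[1], dim[1], dim[2])
  gy <- matrix(seq_len(dim[2]) / dim[2], dim[1], dim[2], byrow = TRUE)
  u2d <- 0.5 + 0.5 * sin(2.1 * pi * gx + 0.7) * cos(1.7 * pi * gy + 0.3)
  v2d <- 0.5 + 0.5 * cos(1.3 * pi * gx + 1.1) * sin(2.3 * pi * gy + 0.5)
  zmod <- 0.85 + 0.15 * sin(seq_len(dim[3]) / dim[3] * pi)
  u <- array(0, dim); v <- array(0, dim)
  for (k in seq_len(dim[3])) {
    u[, , k] <- pmin(1, pmax(0, u2d * zmod[k]))
    v[, , k] <- pmin(1, pmax(0, v2d * zmod[k]))
  }

  kt <- array(0, dim)
  ve <- array(0, dim)
  rim <- tumor & !core
  kt[rim] <- ktrans_range[1] + diff(ktrans_range) * u[rim]
  ve[rim] <- ve_range[1] + diff(ve_range) * v[rim]
  kt[muscle] <- ktrans_muscle
  ve[muscle] <- ve_muscle
  ve[core] <- ve_range[1] + diff(ve_range) * v[core]  # tissue exists, no transfer

  t1 <- array(NA_real_, dim)
  t1[muscle] <- t1_muscle
  t1[rim] <- t1_tumor
  t1[core] <- t1_core
  m0map <- array(0, dim)
  tissue <- tumor | muscle
  m0map[tissue] <- m0

  structure(list(
    t1_map = t1, m0_map = m0map, ktrans_map = kt, ve_map = ve,
    tumor_mask = tumor, nonenhanced_core_mask = core, muscle_mask = muscle,
    tissue_mask = tissue, dim = dim, voxel_size = voxel_size,
    # optical axis passes through the tumor center; in-plane it anchors the
    # muscle reference blocks just beyond the tumor border in the slab
    beam_axis = c(tumor_center[1],
                  if (length(muscle_box$y)) min(muscle_box$y) + 3
                  else tumor_center[2])
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Digital phantom %s, voxel %s mm\n",
              paste(x$dim, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  cat(sprintf("  tumor %d voxels (core %d non-enhancing), muscle %d voxels\n",
              sum(x$tumor_mask), sum(x$nonenhanced_core_mask),
              sum(x$muscle_mask)))
  invisible(x)
}

# Evaluate a function with a temporarily-seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add measurement noise to a signal array
#'
#' Gaussian noise adds `sigma`-scaled normal deviates; Rician noise models
#' magnitude MRI, \eqn{|S + n_1 + i n_2|} with independent
#' \eqn{n_1, n_2 \sim N(0, \sigma^2)}. For a zero-signal voxel the Rician
#' mean is \eqn{\sigma\sqrt{\pi/2}}.
#'
#' @param x Numeric array of noiseless signal.
#' @param noise A [noise_spec()]. `sigma = 0` returns `x` unchanged.
#' @return Array of the same shape.
#' @export
add_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(x)
  with_seed(noise$seed, {
    n <- length(x)
    if (noise$model == "gaussian") {
      x + array(stats::rnorm(n, 0, noise$sigma), dim(x) %||% n)
    } else {
      re <- x + stats::rnorm(n, 0, noise$sigma)
      im <- stats::rnorm(n, 0, noise$sigma)
      array(sqrt(re^2 + im^2), dim(x) %||% n)
    }
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the VFA and DCE acquisitions of a phantom
#'
#' Forward model per tissue voxel: the AIF drives a Tofts-Kermode tissue
#' concentration curve from the true (Ktrans, ve); \eqn{R_1(t) = R_{1,pre} +
#' r_1 C(t)} converts concentration to relaxation rate; the spoiled
#' gradient-echo equation converts R1 to signal at the protocol's DCE flip
#' angle, and separately at each VFA flip angle for the pre-contrast series.
#' Noise is then added per `noise`; identical seeds give identical output.
#' The dynamic series is assumed to be in steady state from the first frame.
#'
#' @param truth A [phantom_truth()].
#' @param protocol A [scan_protocol()].
#' @param aif An [aif_params()].
#' @param noise A [noise_spec()].
#' @return List with components `vfa` (class `vfa_series`: `signal`
#'   `[x,y,z,angle]`, `angles`, `protocol`, `mask`) and `dce` (class
#'   `dce_series`: `signal` `[x,y,z,frame]`, `times`, `protocol`, `mask`).
#' @export
simulate_study <- function(truth, protocol = scan_protocol(),
                           aif = aif_params(), noise = noise_spec()) {
  stopifnot(inherits(truth, "phantom_truth"),
            inherits(protocol, "scan_protocol"),
            inherits(aif, "aif_params"))
  d <- truth$dim
  mask <- truth$tissue_mask
  idx <- which(mask)
  t1 <- truth$t1_map[idx]
  m0 <- truth$m0_map[idx]
  r1pre <- 1 / t1

  na <- length(protocol$vfa_flip_angles)
  vfa_sig <- array(0, c(d, na))
  for (j in seq_len(na)) {
    sl <- array(0, d)
    sl[idx] <- spgr_signal(m0, t1, protocol$vfa_flip_angles[j],
                           protocol$tr_vfa)
    vfa_sig[, , , j] <- sl
  }

  times <- dce_times(protocol)
  nt <- length(times)
  kt <- truth$ktrans_map[idx]
  ve <- truth$ve_map[idx]
  # group voxels by unique (ktrans, ve): the smooth fields repeat across z
  key <- paste(kt, ve)
  grp <- match(key, unique(key))
  ukt <- kt[!duplicated(key)]
  uve <- ve[!duplicated(key)]
  curves <- matrix(0, length(ukt), nt)
  for (g in seq_along(ukt)) {
    if (ukt[g] > 0)
      curves[g, ] <- tissue_concentration(times, ukt[g], uve[g], aif,
                                          protocol$injection_time)
  }
  conc <- curves[grp, , drop = FALSE]           # nvox x nt
  r1t <- conc * protocol$r1_relaxivity + r1pre  # r1pre recycles down columns
  a <- protocol$fa_dce * pi / 180
  e1 <- exp(-protocol$tr_dce * r1t)
  sig_vox <- m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))

  dce_sig <- array(0, c(d, nt))
  flat <- matrix(dce_sig, prod(d), nt)
  flat[idx, ] <- sig_vox
  dce_sig <- array(flat, c(d, nt))

  vfa_sig <- add_noise(vfa_sig, noise)
  noise2 <- noise
  noise2$seed <- noise$seed + 1L   # independent realization for the dynamic series
  dce_sig <- add_noise(dce_sig, noise2)

  vfa <- structure(list(signal = vfa_sig, angles = protocol$vfa_flip_angles,
                        protocol = protocol, mask = mask),
                   class = "vfa_series")
  dce <- structure(list(signal = dce_sig, times = times, protocol = protocol,
                        mask = mask),
                   class = "dce_series")
  list(vfa = vfa, dce = dce)
}

#' Construct a VFA series object from raw data
#'
#' @param signal 4-D array `[x, y, z, angle]` in signal units.
#' @param angles Flip angles (degrees), strictly increasing, length matching
#'   the 4th dimension.
#' @param protocol A [scan_protocol()].
#' @param mask Logical 3-D array of voxels to analyse.
#' @return Object of class `vfa_series`.
#' @export
vfa_series <- function(signal, angles, protocol, mask) {
  stopifnot(length(dim(signal)) == 4, dim(signal)[4] == length(angles),
            length(angles) >= 2, all(diff(angles) > 0),
            identical(dim(mask), dim(signal)[1:3]))
  structure(list(signal = signal, angles = as.numeric(angles),
                 protocol = protocol, mask = mask), class = "vfa_series")
}

#' Construct a DCE series object from raw data
#'
#' @param signal 4-D array `[x, y, z, frame]`.
#' @param times Frame times (seconds), strictly increasing.
#' @param protocol A [scan_protocol()].
#' @param mask Logical 3-D array.
#' @return Object of class `dce_series`.
#' @export
dce_series <- function(signal, times, protocol, mask) {
  stopifnot(length(dim(signal)) == 4, dim(signal)[4] == length(times),
            all(diff(times) > 0), identical(dim(mask), dim(signal)[1:3]),
            sum(times < protocol$injection_time) >= 3)
  structure(list(signal = signal, times = as.numeric(times),
                 protocol = protocol, mask = mask), class = "dce_series")
}
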