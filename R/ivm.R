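#' Calibrated fluorescence image
#'
#' Wraps a single-channel intensity image together with its calibration:
#' pixel area, dark current, the daily reference-standard gain factor, and
#' the tissue autofluorescence level (already expressed per 5000 um^2).
#'
#' @param pixels Numeric matrix of intensities.
#' @param pixel_area Pixel area in um^2, `> 0`.
#' @param channel One of `"gfp"`, `"nir"`, `"rhodamine"`.
#' @param dark_current Dark-current offset (intensity units).
#' @param reference_factor Dimensionless daily gain, `> 0`.
#' @param autofluorescence Autofluorescence integrated density per 5000 um^2.
#' @return Object of class `fluor_image`.
#' @export
fluorescence_image <- function(pixels, pixel_area,
                               channel = c("nir", "gfp", "rhodamine"),
                               dark_current = 0, reference_factor = 1,
                               autofluorescence = 0) {
  channel <- match.arg(channel)
  stopifnot(is.matrix(pixels), pixel_area > 0, reference_factor > 0,
            autofluorescence >= 0)
  structure(list(pixels = pixels, pixel_area = pixel_area, channel = channel,
                 dark_current = dark_current,
                 reference_factor = reference_factor,
                 autofluorescence = autofluorescence),
            class = "fluor_image")
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf("%s fluorescence image %dx%d px (%.3g um^2/px), dark %.3g, ref %.3g\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_area,
              x$dark_current, x$reference_factor))
  invisible(x)
}

#' Corrected integrated density of an ROI
#'
#' Integrated density (sum of dark-current-subtracted pixel intensities) is
#' normalized to a reference area of 5000 um^2 - integrated density rather
#' than mean intensity, because receptor-specific binding makes the
#' fluorescence spatially heterogeneous - then divided by the daily
#' reference-standard factor and reduced by the ROI's autofluorescence:
#' \deqn{ID_{corr} = \frac{5000}{n_{px} A_{px}} \sum_{ROI}(I - dark) /
#'   f_{ref} - AF.}
#' Negative corrected values are clipped to 0 and flagged.
#'
#' @param img A [fluorescence_image()].
#' @param roi Logical matrix the size of the image, or integer pixel indices.
#' @return Object of class `roi_measurement`: `integrated_density` (the
#'   corrected, per-5000-um^2 value), `raw_density`, `n_pixels`, `clipped`.
#' @export
corrected_density <- function(img, roi) {
  stopifnot(inherits(img, "fluor_image"))
  if (is.logical(roi)) {
    stopifnot(identical(dim(roi), dim(img$pixels)))
    roi <- which(roi)
  }
  if (length(roi) == 0) stop("empty ROI")
  id <- sum(img$pixels[roi] - img$dark_current)
  id_norm <- id * 5000 / (length(roi) * img$pixel_area)
  id_corr <- id_norm / img$reference_factor - img$autofluorescence
  clipped <- id_corr < 0
  structure(list(integrated_density = max(id_corr, 0),
                 raw_density = id_norm, n_pixels = length(roi),
                 clipped = clipped, channel = img$channel),
            class = "roi_measurement")
}

#' @export
print.roi_measurement <- function(x, ...) {
  cat(sprintf("ROI (%d px, %s): corrected integrated density %.4g per 5000 um^2%s\n",
              x$n_pixels, x$channel, x$integrated_density,
              if (x$clipped) " [clipped at 0]" else ""))
  invisible(x)
}

#' Inverse-variance weighted mean
#'
#' Weighted mean of per-ROI (or per-animal) mean intensities, each weighted
#' by its own standard deviation: \eqn{w_i = 1/sd_i^2}, \eqn{\bar{x}_w =
#' \sum w_i x_i / \sum w_i}. With equal SDs this reduces exactly to the
#' arithmetic mean. The reported spread is by default the uncertainty of the
#' weighted mean, \eqn{\sqrt{1/\sum w_i}}; `spread = "sample"` instead gives
#' the weighted sample SD about the weighted mean. Zero or missing SDs would
#' carry infinite weight, so they are capped at the smallest positive SD in
#' the set (all-zero SDs fall back to equal weights).
#'
#' @param values Numeric vector of means.
#' @param sds Numeric vector of their SDs, same length, `>= 0`.
#' @param spread `"uncertainty"` (default) or `"sample"`.
#' @return Object of class `weighted_summary`: `wmean`, `wsd`, `n`.
#' @export
weighted_mean_sd <- function(values, sds, spread = c("uncertainty", "sample")) {
  spread <- match.arg(spread)
  stopifnot(length(values) == length(sds), length(values) >= 1,
            all(sds >= 0))
  pos <- sds[sds > 0]
  sds2 <- if (length(pos) == 0) rep(1, length(sds)) else pmax(sds, min(pos))
  w <- 1 / sds2^2
  wmean <- sum(w * values) / sum(w)
  wsd <- if (spread == "uncertainty") {
    sqrt(1 / sum(w))
  } else if (length(values) > 1) {
    sqrt(sum(w * (values - wmean)^2) / sum(w) *
           length(values) / (length(values) - 1))
  } else {
    sds2[1]
  }
  structure(list(wmean = wmean, wsd = wsd, n = length(values),
                 spread = spread), class = "weighted_summary")
}

#' @export
print.weighted_summary <- function(x, ...) {
  cat(sprintf("weighted mean %.4g +/- %.4g (n = %d, %s spread)\n",
              x$wmean, x$wsd, x$n, x$spread))
  invisible(x)
}

#' Tumor-to-normal fluorescence ratio
#'
#' Ratio of the tumor and normal-tissue weighted mean intensities, with
#' first-order (delta-method) error propagation:
#' \deqn{TNR = \bar{x}_T/\bar{x}_N, \quad
#'  \sigma_{TNR} = \sqrt{(\sigma_T/\bar{x}_N)^2 +
#'    (\bar{x}_T \sigma_N / \bar{x}_N^2)^2}.}
#'
#' @param tumor,normal `weighted_summary` objects; `normal$wmean` must be
#'   positive.
#' @return List with `ratio` and `sd`.
#' @export
tnr <- function(tumor, normal) {
  stopifnot(inherits(tumor, "weighted_summary"),
            inherits(normal, "weighted_summary"))
  if (normal$wmean <= 0) stop("normal-tissue mean must be positive")
  r <- tumor$wmean / normal$wmean
  s <- sqrt((tumor$wsd / normal$wmean)^2 +
              (tumor$wmean * normal$wsd / normal$wmean^2)^2)
  list(ratio = r, sd = s)
}

#' Spearman colocalization of two fluorescence channels
#'
#' Spearman's rank correlation between two channels over an ROI, computed
#' after per-channel dark-current subtraction (which cannot change ranks but
#' mirrors the processing applied before colocalization analysis). Ties
#' receive average ranks. No intensity threshold is applied. A constant
#' channel has no defined rank correlation; `rho` is then `NA`.
#'
#' @param green,red [fluorescence_image()] objects of identical size.
#' @param roi Logical matrix or pixel indices; at least 3 pixels.
#' @return Object of class `coloc_result`: `rho`, `n_pixels`.
#' @export
spearman_coloc <- function(green, red, roi = NULL) {
  stopifnot(inherits(green, "fluor_image"), inherits(red, "fluor_image"),
            identical(dim(green$pixels), dim(red$pixels)))
  if (is.null(roi)) roi <- seq_along(green$pixels)
  if (is.logical(roi)) roi <- which(roi)
  if (length(roi) < 3) stop("need >= 3 ROI pixels")
  g <- green$pixels[roi] - green$dark_current
  r <- red$pixels[roi] - red$dark_current
  rho <- if (stats::sd(g) == 0 || stats::sd(r) == 0) NA_real_
  else stats::cor(g, r, method = "spearman")
  structure(list(rho = rho, n_pixels = length(roi)), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Spearman colocalization rho = %s over %d pixels\n",
              if (is.na(x$rho)) "NA (constant channel)" else
                sprintf("%.3f", x$rho), x$n_pixels))
  invisible(x)
}

#' Synthetic two-channel microscopy image pair
#'
#' Generates a green (tumor-cell GFP) and red (probe) channel sharing a
#' common membrane-like structure. The red channel mixes the shared
#' structure, weighted by `coloc_fraction`, with an independent structure
#' and Gaussian noise, so the expected rank correlation between the channels
#' increases monotonically with `coloc_fraction` in [0, 1].
#'
#' @param n Image side length in pixels.
#' @param coloc_fraction Weight of the shared structure in the red channel.
#' @param noise_sd Gaussian noise SD relative to unit structure amplitude.
#' @param pixel_area Pixel area (um^2).
#' @param seed Integer seed.
#' @return List of two [fluorescence_image()]s, `green` and `red`.
#' @export
simulate_coloc_pair <- function(n = 64, coloc_fraction = 0.5, noise_sd = 0.2,
                                pixel_area = 1, seed = 1L) {
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1, noise_sd >= 0)
  with_seed(seed, {
    smooth2d <- function() {
      f <- matrix(stats::rnorm(16 * 16), 16, 16)
      # bilinear upsample to n x n
      xi <- seq(1, 16, length.out = n)
      i0 <- pmin(floor(xi), 15); fx <- xi - i0
      up <- f[i0, ] * (1 - fx) + f[i0 + 1, ] * fx
      up <- t(t(up[, i0]) * (1 - fx) + t(up[, i0 + 1]) * fx)
      up
    }
    shared <- exp(smooth2d())      # positive membrane-like intensity field
    indep <- exp(smooth2d())
    gn <- shared + noise_sd * matrix(stats::rnorm(n * n), n, n)
    rd <- coloc_fraction * shared + (1 - coloc_fraction) * indep +
      noise_sd * matrix(stats::rnorm(n * n), n, n)
    list(green = fluorescence_image(gn, pixel_area, "gfp"),
         red = fluorescence_image(rd, pixel_area, "nir"))
  })
}
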