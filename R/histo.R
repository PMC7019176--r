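#' Histology section container
#'
#' Holds the fluorescence images and masks of one tumor section: the Hoechst
#' 33342 perfusion-marker image, optionally the CD31 endothelial stain, the
#' tumor mask, the manually segmented necrosis mask, and the manually chosen
#' Hoechst intensity threshold separating perfused from non-perfused tissue.
#'
#' @param hoechst Numeric intensity matrix.
#' @param tumor_mask Logical matrix, same size.
#' @param necrosis_mask Logical matrix, subset of `tumor_mask` (manual
#'   segmentation input).
#' @param threshold Manually selected Hoechst threshold, `> 0`. Required:
#'   there is no automatic default (see [otsu_threshold()] for an explicit
#'   helper).
#' @param cd31 Optional CD31 intensity matrix.
#' @return Object of class `histo_section`.
#' @export
histo_section <- function(hoechst, tumor_mask, necrosis_mask, threshold,
                          cd31 = NULL) {
  stopifnot(is.matrix(hoechst), identical(dim(hoechst), dim(tumor_mask)),
            identical(dim(hoechst), dim(necrosis_mask)))
  if (missing(threshold) || is.null(threshold))
    stop("a manually selected Hoechst threshold is required")
  stopifnot(threshold > 0)
  if (any(necrosis_mask & !tumor_mask))
    stop("necrosis_mask must be a subset of tumor_mask")
  structure(list(hoechst = hoechst, cd31 = cd31, tumor_mask = tumor_mask,
                 necrosis_mask = necrosis_mask, threshold = threshold),
            class = "histo_section")
}

#' Classify tumor tissue as perfused or non-perfused
#'
#' Applies the section's manually selected intensity threshold to the
#' Hoechst image: tissue is perfused where `hoechst >= threshold`, evaluated
#' within the tumor mask only.
#'
#' @param section A [histo_section()].
#' @return Logical matrix: `TRUE` = perfused (within tumor), `FALSE`
#'   elsewhere.
#' @export
classify_perfusion <- function(section) {
  stopifnot(inherits(section, "histo_section"))
  section$hoechst >= section$threshold & section$tumor_mask
}

#' Necrosis and perfusion fractions of a tumor section
#'
#' \itemize{
#'   \item necrotic fraction: `100 * |necrosis| / |tumor|`
#'   \item non-perfused fraction: `100 * |tumor \ perfused| / |tumor|`
#'   \item overlap: `100 * |necrosis & non-perfused| / |necrosis|` - the
#'     share of the necrotic area that is also non-perfused (0 when the
#'     section has no necrosis).
#' }
#' Masks are assumed pre-registered.
#'
#' @param section A [histo_section()].
#' @param perfused Logical perfusion mask, e.g. from [classify_perfusion()].
#' @return Object of class `perfusion_stats` with fields
#'   `necrotic_fraction`, `nonperfused_fraction`,
#'   `necrotic_nonperfused_overlap` (all percent).
#' @export
perfusion_stats <- function(section, perfused = classify_perfusion(section)) {
  stopifnot(inherits(section, "histo_section"),
            identical(dim(perfused), dim(section$tumor_mask)))
  ntum <- sum(section$tumor_mask)
  if (ntum == 0) stop("empty tumor mask")
  nonperf <- section$tumor_mask & !perfused
  nnec <- sum(section$necrosis_mask)
  structure(list(
    necrotic_fraction = 100 * nnec / ntum,
    nonperfused_fraction = 100 * sum(nonperf) / ntum,
    necrotic_nonperfused_overlap =
      if (nnec == 0) 0 else 100 * sum(section$necrosis_mask & nonperf) / nnec,
    n_tumor = ntum, n_necrosis = nnec, n_nonperfused = sum(nonperf)
  ), class = "perfusion_stats")
}

#' @export
print.perfusion_stats <- function(x, ...) {
  cat(sprintf(
    "Section: %.1f%% necrotic, %.1f%% non-perfused, overlap %.1f%% of necrosis\n",
    x$necrotic_fraction, x$nonperfused_fraction,
    x$necrotic_nonperfused_overlap))
  invisible(x)
}

#' Otsu threshold helper
#'
#' Optional helper for exploratory work: an automatic global threshold from
#' Otsu's method (via the EBImage package). It is never applied implicitly -
#' [histo_section()] always requires an explicit, manually chosen threshold.
#'
#' @param x Numeric matrix with values in `[0, 1]` (rescale first if needed).
#' @param levels Number of histogram levels passed to `EBImage::otsu()`.
#' @return Threshold value.
#' @export
otsu_threshold <- function(x, levels = 256) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("otsu_threshold() needs the EBImage package")
  EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = levels)
}
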