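#' Non-enhanced fraction of an ROI
#'
#' Percentage of ROI voxels classified non-enhanced:
#' `100 * #(non-enhanced & roi) / #roi`. Voxels whose classification is
#' undefined (`NA`, e.g. excluded by the T1 fit) count in the denominator but
#' never in the numerator, so the reported fraction is conservative.
#'
#' @param enhanced Logical array from `conc_maps$enhanced` (`NA` = undefined).
#' @param roi Logical array, same shape, non-empty.
#' @return Percentage in `[0, 100]`.
#' @export
nonenhanced_fraction <- function(enhanced, roi) {
  stopifnot(identical(dim(enhanced), dim(roi)))
  n <- sum(roi)
  if (n == 0) stop("empty ROI")
  100 * sum(!enhanced & roi, na.rm = TRUE) / n
}

#' Place square muscle reference ROIs near the tumor
#'
#' Selects the four central slices of the tumor's slice extent (the middle
#' four, ties resolved towards smaller indices) and places, in each, one
#' `block x block` in-plane pixel block: the candidate closest to the light
#' beam axis whose bounding box, expanded by `spacing` pixels, contains no
#' tumor pixel (i.e. at least one pixel spacing to the tumor border).
#' Distance is Euclidean from block center to `beam_axis`; exact ties go to
#' the smaller row, then column index. Slices with no feasible block are
#' skipped with a warning.
#'
#' @param tumor_mask Logical 3-D array.
#' @param beam_axis In-plane coordinate pair (x, y) of the beam axis.
#' @param block Block side length in pixels (default 5).
#' @param spacing Minimum spacing to the tumor border in pixels (default 1).
#' @param n_slices Number of central slices to use (default 4).
#' @return Object of class `roi_set`: list `blocks` of `(slice, rows, cols)`,
#'   the combined logical `mask`, and the inputs.
#' @export
place_muscle_rois <- function(tumor_mask, beam_axis, block = 5L,
                              spacing = 1L, n_slices = 4L) {
  stopifnot(length(dim(tumor_mask)) == 3, length(beam_axis) == 2)
  zs <- which(apply(tumor_mask, 3, any))
  if (length(zs) < n_slices)
    stop(sprintf("tumor intersects only %d slices; need >= %d",
                 length(zs), n_slices))
  zmin <- min(zs); zmax <- max(zs)
  k <- zmax - zmin + 1
  start <- zmin + floor((k - n_slices) / 2)
  slices <- start:(start + n_slices - 1)

  d <- dim(tumor_mask)
  blocks <- list()
  mask <- array(FALSE, d)
  for (z in slices) {
    sl <- tumor_mask[, , z]
    b <- find_block(sl, beam_axis, block, spacing)
    if (is.null(b)) {
      warning(sprintf("no feasible %dx%d block in slice %d; skipped",
                      block, block, z))
      next
    }
    blocks[[length(blocks) + 1]] <- list(slice = z, rows = b$rows,
                                         cols = b$cols)
    mask[b$rows, b$cols, z] <- TRUE
  }
  structure(list(blocks = blocks, mask = mask, beam_axis = beam_axis,
                 block = block, spacing = spacing, slices = slices),
            class = "roi_set")
}

# Exhaustive feasible-block search in one slice using a summed-area table.
find_block <- function(sl, beam_axis, block, spacing) {
  nr <- nrow(sl); nc <- ncol(sl)
  if (nr < block || nc < block) return(NULL)
  # integral image of the tumor mask
  s <- t(apply(apply(sl, 2, cumsum), 1, cumsum))  # s[i, j] = sum rows<=i, cols<=j
  sat <- matrix(0, nr + 1, nc + 1)
  sat[-1, -1] <- s
  boxsum <- function(r1, r2, c1, c2) {
    r1 <- max(r1, 1); c1 <- max(c1, 1)
    r2 <- min(r2, nr); c2 <- min(c2, nc)
    sat[r2 + 1, c2 + 1] - sat[r1, c2 + 1] - sat[r2 + 1, c1] + sat[r1, c1]
  }
  best <- NULL
  for (i in seq_len(nr - block + 1)) {
    for (j in seq_len(nc - block + 1)) {
      if (boxsum(i - spacing, i + block - 1 + spacing,
                 j - spacing, j + block - 1 + spacing) > 0) next
      ctr <- c(i + (block - 1) / 2, j + (block - 1) / 2)
      d2 <- sum((ctr - beam_axis)^2)
      if (is.null(best) || d2 < best$d2 -1e-12 ||
          (abs(d2 - best$d2) <= 1e-12 &&
           (i < best$i || (i == best$i && j < best$j)))) {
        best <- list(i = i, j = j, d2 = d2)
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(rows = best$i:(best$i + block - 1),
       cols = best$j:(best$j + block - 1), dist = sqrt(best$d2))
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("Muscle ROI set: %d blocks of %dx%d pixels (slices %s)\n",
              length(x$blocks), x$block, x$block,
              paste(vapply(x$blocks, `[[`, 0L, "slice"), collapse = ", ")))
  invisible(x)
}

#' Study-level summary of the pharmacokinetic analysis
#'
#' Aggregates the voxelwise results into the quantities reported per animal
#' and time point: the non-enhanced fraction of the tumor and of the muscle
#' reference ROIs, mean Ktrans over enhanced-and-converged voxels in each
#' compartment, mean tumor AUC, and voxel counts. Means deliberately cover
#' enhanced voxels only, in both compartments. Empty compartments yield `NA`
#' fields rather than errors.
#'
#' @param fit A `tofts_map` from [pk_map()].
#' @param conc A `conc_maps` object.
#' @param rois A `roi_set` from [place_muscle_rois()].
#' @param tumor_mask Logical 3-D tumor segmentation.
#' @return Object of class `study_summary` (also a one-row data frame via
#'   [as.data.frame.study_summary()]).
#' @export
summarize_study <- function(fit, conc, rois, tumor_mask) {
  stopifnot(inherits(fit, "tofts_map"), inherits(conc, "conc_maps"),
            inherits(rois, "roi_set"),
            identical(dim(tumor_mask), dim(fit$ktrans)))
  auc <- auc_map(conc)
  use <- fit$fitted_mask & !is.na(fit$converged) & fit$converged
  mean_or_na <- function(x, m) if (sum(m) == 0) NA_real_ else mean(x[m])
  s <- list(
    nonenhanced_fraction_tumor = nonenhanced_fraction(conc$enhanced,
                                                      tumor_mask),
    nonenhanced_fraction_muscle = nonenhanced_fraction(conc$enhanced,
                                                       rois$mask),
    mean_ktrans_tumor_enhanced = mean_or_na(fit$ktrans, use & tumor_mask),
    mean_ktrans_muscle = mean_or_na(fit$ktrans, use & rois$mask),
    mean_auc_tumor = mean(auc[tumor_mask & conc$valid], na.rm = TRUE),
    n_tumor = sum(tumor_mask),
    n_tumor_enhanced = sum(use & tumor_mask),
    n_muscle_roi = sum(rois$mask),
    n_muscle_enhanced = sum(use & rois$mask)
  )
  structure(s, class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Study summary\n")
  cat(sprintf("  tumor: %.1f%% non-enhanced (%d voxels); mean Ktrans %.3g min^-1 over %d enhanced\n",
              x$nonenhanced_fraction_tumor, x$n_tumor,
              x$mean_ktrans_tumor_enhanced, x$n_tumor_enhanced))
  cat(sprintf("  muscle ROI: %.1f%% non-enhanced (%d voxels); mean Ktrans %.3g min^-1\n",
              x$nonenhanced_fraction_muscle, x$n_muscle_roi,
              x$mean_ktrans_muscle))
  cat(sprintf("  mean tumor AUC %.4g mM*s\n", x$mean_auc_tumor))
  invisible(x)
}

#' Coerce a study summary to a one-row data frame
#'
#' @param x A `study_summary`.
#' @param ... Unused.
#' @return A one-row `data.frame` with one column per summary field.
#' @export
as.data.frame.study_summary <- function(x, ...) {
  as.data.frame(unclass(x), row.names = "")
}
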