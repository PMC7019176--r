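#' Write a volume as NIfTI-1
#'
#' Thin wrapper over [RNifti::writeNifti()]. Logical arrays are written as
#' uint8 masks; numeric arrays as float32 (or the template's datatype). The
#' affine/pixdim of `template` is carried untouched when supplied, so
#' coordinates never drift between pipeline stages. Voxel indices are
#' 0-based internally, axis order `[x, y, z, t]`.
#'
#' @param x 3-D or 4-D array (numeric or logical).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Optional length-3 voxel size in mm (ignored if
#'   `template` given).
#' @param template Optional `niftiImage` or array whose header is reused.
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = NULL, template = NULL) {
  dt <- if (is.logical(x)) "uint8" else "float"
  if (is.logical(x)) x <- array(as.integer(x), dim(x))
  img <- if (!is.null(template)) RNifti::asNifti(x, reference = template)
  else RNifti::asNifti(x)
  if (is.null(template) && !is.null(voxel_size))
    RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(x)) - 3))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A `niftiImage` array (header preserved as attributes).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("input volume not found: ", path)
  RNifti::readNifti(path)
}

#' Read a fluorescence TIFF with required pixel-size calibration
#'
#' Reads a single-channel TIFF into a [fluorescence_image()]. The physical
#' pixel area is mandatory: if `pixel_area` is not supplied it is derived
#' from the TIFF resolution tags, and an error naming the missing
#' calibration is raised when neither is available - never a silent default.
#'
#' @param path TIFF path.
#' @param pixel_area Pixel area in um^2, or `NULL` to use the file's
#'   resolution tags (interpreted as pixels per centimetre or inch).
#' @param ... Passed to [fluorescence_image()] (channel, dark_current, ...).
#' @return A `fluor_image`.
#' @export
read_fluorescence_tiff <- function(path, pixel_area = NULL, ...) {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  img <- tiff::readTIFF(path, info = TRUE)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1)
      stop("multi-channel TIFF: read channels separately")
    img <- img[, , 1]
  }
  if (is.null(pixel_area)) {
    xr <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit") %||% "inch"
    if (is.null(xr) || !is.finite(xr) || xr <= 0)
      stop("TIFF carries no pixel size; supply pixel_area (um^2 per pixel)")
    um_per_px <- switch(as.character(unit),
                        inch = 25400 / xr, cm = 10000 / xr, 10000 / xr)
    pixel_area <- um_per_px^2
  }
  fluorescence_image(img, pixel_area = pixel_area, ...)
}

#' Write a matrix as a 16-bit TIFF
#'
#' Intensities are stored in `[0, 1]`; values outside are an error so that
#' scaling is always an explicit, recorded choice of the caller.
#'
#' @param x Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tiff_image <- function(x, path) {
  stopifnot(is.matrix(x))
  if (min(x) < 0 || max(x) > 1)
    stop("intensities must be pre-scaled to [0, 1]")
  tiff::writeTIFF(x, path, bits.per.sample = 16)
  invisible(path)
}

#' Reproducible pipeline run configuration
#'
#' Bundles everything a full phantom-to-summary run depends on. A
#' configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]), and every run writes a
#' provenance record (config + package version + seed) next to its outputs.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving all randomness of the run.
#' @param noise_model,noise_sigma Noise specification for the simulation.
#' @param protocol A [scan_protocol()].
#' @param aif An [aif_params()].
#' @param phantom Named list of [phantom_truth()] arguments (geometry).
#' @param write_volumes Write NIfTI parameter maps (the summary CSV and
#'   provenance JSON are always written).
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, noise_model = "rician",
                       noise_sigma = 0, protocol = scan_protocol(),
                       aif = aif_params(), phantom = list(),
                       write_volumes = TRUE) {
  stopifnot(inherits(protocol, "scan_protocol"), inherits(aif, "aif_params"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 noise_model = noise_model, noise_sigma = noise_sigma,
                 protocol = unclass(protocol), aif = unclass(aif),
                 phantom = phantom, write_volumes = isTRUE(write_volumes)),
            class = "run_config")
}

#' Serialize a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML path written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  x <- yaml::read_yaml(path)
  run_config(out_dir = x$out_dir, seed = x$seed,
             noise_model = x$noise_model, noise_sigma = x$noise_sigma,
             protocol = do.call(scan_protocol, x$protocol),
             aif = do.call(aif_params, x$aif),
             phantom = x$phantom %||% list(),
             write_volumes = x$write_volumes)
}

#' Run the full phantom-to-summary analysis pipeline
#'
#' Executes phantom simulation, VFA T1 mapping, concentration conversion and
#' enhancement classification, voxelwise Tofts-Kermode fitting, muscle ROI
#' placement and study summarization in order, logging voxel counts and
#' exclusions at every stage boundary so analysis exclusions stay auditable.
#' Identical configuration and seed yield byte-identical summary outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage logging.
#' @return The `study_summary`, invisibly; side effects: `summary.csv`,
#'   `provenance.json` and (optionally) NIfTI maps under `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_ <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  protocol <- do.call(scan_protocol, config$protocol)
  aif <- do.call(aif_params, config$aif)

  truth <- do.call(phantom_truth, config$phantom)
  log_("phantom: %d tissue voxels (%d tumor, %d core, %d muscle)",
       sum(truth$tissue_mask), sum(truth$tumor_mask),
       sum(truth$nonenhanced_core_mask), sum(truth$muscle_mask))
  noise <- noise_spec(config$noise_model, config$noise_sigma, config$seed)
  sim <- simulate_study(truth, protocol, aif, noise)

  r1 <- fit_t1_vfa(sim$vfa)
  log_("t1map: %d valid / %d masked voxels (%d excluded)",
       sum(r1$valid), sum(r1$mask), sum(r1$mask) - sum(r1$valid))

  conc <- signal_to_concentration(sim$dce, r1)
  log_("conc: %d analysed voxels, %d enhanced, %d non-enhanced",
       sum(conc$valid), sum(conc$enhanced, na.rm = TRUE),
       sum(!conc$enhanced, na.rm = TRUE))

  fit <- pk_map(conc, aif)
  log_("pk: %d fitted voxels, %d converged", sum(fit$fitted_mask),
       sum(fit$converged, na.rm = TRUE))

  rois <- place_muscle_rois(truth$tumor_mask, truth$beam_axis)
  summ <- summarize_study(fit, conc, rois, truth$tumor_mask)

  if (config$write_volumes) {
    vs <- truth$voxel_size
    write_volume(truth$ktrans_map, file.path(config$out_dir, "truth_ktrans.nii.gz"), vs)
    write_volume(r1$t1, file.path(config$out_dir, "t1.nii.gz"), vs)
    write_volume(r1$valid, file.path(config$out_dir, "t1_valid.nii.gz"), vs)
    enh <- conc$enhanced; enh[is.na(enh)] <- FALSE
    write_volume(enh, file.path(config$out_dir, "enhanced.nii.gz"), vs)
    write_volume(auc_map(conc), file.path(config$out_dir, "auc.nii.gz"), vs)
    write_volume(fit$ktrans, file.path(config$out_dir, "ktrans.nii.gz"), vs)
    write_volume(fit$ve, file.path(config$out_dir, "ve.nii.gz"), vs)
    write_volume(fit$kep, file.path(config$out_dir, "kep.nii.gz"), vs)
  }
  utils::write.csv(as.data.frame(summ),
                   file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  prov <- list(package = "pdtvasc",
               version = as.character(utils::packageVersion("pdtvasc")),
               seed = config$seed, config = unclass(config),
               n_valid = sum(r1$valid), n_fitted = sum(fit$fitted_mask),
               n_excluded_t1 = sum(r1$mask) - sum(r1$valid))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_("summary written to %s", file.path(config$out_dir, "summary.csv"))
  invisible(summ)
}
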