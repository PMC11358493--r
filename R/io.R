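# File formats: float TIFF images with JSON sidecar metadata (no image is
# ever consumed without explicit voxel dimensions), stack reading/writing,
# and validated pipeline configuration.

#' Write / read a float TIFF image with a JSON sidecar
#'
#' Images are stored as 32-bit TIFF normalized by a power-of-two scale
#' recorded in the sidecar. Integer-valued data (count maps) round-trip
#' exactly (an `integer_data` sidecar flag restores them); continuous data
#' round-trip to within 1 part in 2^32 of full scale. The sidecar
#' (`<path>.json`) carries `pixel_size_um` (mandatory on read),
#' `slice_thickness_um`, `index`, `qc_ok` and any extra metadata.
#'
#' @param data Numeric matrix (values >= 0).
#' @param path Output TIFF path.
#' @param pixel_size_um In-plane pixel size (um).
#' @param slice_thickness_um Slice thickness (um).
#' @param index Slice index in cut order.
#' @param qc_ok Per-slice QC flag (damaged slices are excluded by
#'   aggregations downstream).
#' @param extra Named list of additional sidecar fields.
#' @return `write_image` returns `path` invisibly; `read_image` returns a
#'   list with `data` and the sidecar fields.
#' @export
write_image <- function(data, path, pixel_size_um, slice_thickness_um = 10,
                        index = 1L, qc_ok = TRUE, extra = list()) {
  data <- as.matrix(data)
  if (any(data < 0)) abort("image values must be >= 0", class = "alphadose3d_domain_error")
  mx <- max(data)
  scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
  tiff::writeTIFF(data / scale, path, bits.per.sample = 32L)
  meta <- c(list(pixel_size_um = pixel_size_um,
                 slice_thickness_um = slice_thickness_um,
                 index = index, qc_ok = qc_ok, scale = scale,
                 integer_data = all(data == round(data))), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(paste0("missing metadata sidecar for ", path,
                 " (pixel size must be explicit)"),
          class = "alphadose3d_metadata_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_um)) {
    abort("sidecar lacks pixel_size_um", class = "alphadose3d_metadata_error")
  }
  arr <- tiff::readTIFF(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  # invert the 32-bit quantization (samples are k / 2^32 for
  # k = trunc(value * (2^32 - 1)))
  data <- arr * (4294967296 / 4294967295) * (meta$scale %||% 1)
  if (isTRUE(meta$integer_data)) data <- round(data)
  c(list(data = data), meta)
}

#' Write / read an ordered image stack
#'
#' A stack is a directory of per-slice TIFFs with sidecars; order comes
#' from the sidecar `index`, not the filename.
#'
#' @param slices List of matrices (or a 3D array) to write.
#' @param dir Stack directory.
#' @param pixel_size_um,slice_thickness_um Voxel metadata.
#' @param prefix Filename prefix.
#' @return `write_image_stack` returns `dir` invisibly;
#'   `read_image_stack` returns a list with `slices` (list of per-slice
#'   lists, ordered by index) and `n`.
#' @export
write_image_stack <- function(slices, dir, pixel_size_um,
                              slice_thickness_um = 10, prefix = "slice") {
  if (is.array(slices) && length(dim(slices)) == 3) {
    slices <- lapply(seq_len(dim(slices)[3]), function(z) slices[, , z])
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(slices)) {
    write_image(slices[[i]],
                file.path(dir, sprintf("%s_%03d.tif", prefix, i)),
                pixel_size_um, slice_thickness_um, index = i)
  }
  invisible(dir)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(dir) {
  files <- list.files(dir, pattern = "\\.tiff?$", full.names = TRUE)
  if (length(files) == 0) abort("no TIFF files in stack directory")
  slices <- lapply(files, read_image)
  idx <- vapply(slices, function(s) as.integer(s$index %||% NA_integer_), integer(1))
  if (anyNA(idx)) abort("sidecars lack slice index", class = "alphadose3d_metadata_error")
  slices <- slices[order(idx)]
  list(slices = slices, n = length(slices))
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are
#' rejected; all physical constants must be positive.
#'
#' @param ... Overrides of the default configuration (nested lists are
#'   merged shallowly per section).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    phantom = list(kind = "tumor", shape = c(24, 24, 81),
                   voxel_dims_um = c(39, 39, 10), total_activity_Bq = 3,
                   necrotic_fraction = 0.3),
    calibration = list(geometric_efficiency = 0.5, pileup_loss = 0.238,
                       frame_period_s = 0.040),
    acquisition = list(live_time_s = 86400),
    kernel = list(radial_step_um = 0.5, n_clones = 21),
    gamma = list(dose_tol = 0.10, dist_tol_um = 117, normalization = "local"),
    radiosensitivity = list(alpha = 1.8, beta = 0),
    biokinetics = list(amplitudes = c(60, 15), rates = c(0.08, 0.003),
                       times_h = c(24, 48, 96, 168), n_subjects = 17,
                       inter_subject_cv = 0.3, t_ref_h = 24),
    deescalation = list(reference_ia_kBq = 18.5,
                        ia_grid_kBq = seq(0, 18.5, by = 1.85),
                        kidney_dose_Gy = 6.4, target_tcp = 0.9)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    abort(paste("unknown config keys:", paste(bad, collapse = ", ")),
          class = "alphadose3d_config_error")
  }
  cfg <- defaults
  for (k in names(over)) {
    cfg[[k]] <- if (is.list(defaults[[k]])) {
      bad2 <- setdiff(names(over[[k]]), names(defaults[[k]]))
      if (length(bad2) > 0) {
        abort(paste0("unknown config keys in '", k, "': ",
                     paste(bad2, collapse = ", ")),
              class = "alphadose3d_config_error")
      }
      modifyList(defaults[[k]], over[[k]])
    } else over[[k]]
  }
  pos <- c(cfg$phantom$total_activity_Bq, cfg$calibration$frame_period_s,
           cfg$acquisition$live_time_s, cfg$kernel$radial_step_um,
           cfg$gamma$dose_tol, cfg$gamma$dist_tol_um,
           cfg$radiosensitivity$alpha, cfg$deescalation$reference_ia_kBq)
  if (any(pos <= 0)) {
    abort("physical constants must be positive", class = "alphadose3d_config_error")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML path with the [pipeline_config()] schema.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
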