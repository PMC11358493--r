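# Quantitative digital-autoradiograph (DAR) dosimetry: calibrated activity
# images, cloning-method and sequential dose-rate reconstruction, sparse 3D
# stack assembly, sampling planning, and gamma-index validation.

#' Construct a count image
#'
#' A 2D single-alpha-event count map with acquisition metadata.
#'
#' @param counts Non-negative numeric matrix of event counts.
#' @param pixel_size_um In-plane pixel size (um, > 0).
#' @param slice_thickness_um Physical slice thickness (um).
#' @param live_time Acquisition live time (seconds or unit string).
#' @param start_offset Acquisition start time relative to sacrifice
#'   (seconds or unit string; used for decay correction).
#' @return A `count_image`.
#' @export
count_image <- function(counts, pixel_size_um, slice_thickness_um = 10,
                        live_time = 86400, start_offset = 0) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be >= 0", class = "alphadose3d_domain_error")
  if (pixel_size_um <= 0) abort("pixel_size must be > 0", class = "alphadose3d_domain_error")
  structure(
    list(counts = counts, pixel_size_um = pixel_size_um,
         slice_thickness_um = slice_thickness_um,
         live_time_s = parse_duration(live_time),
         start_offset_s = parse_duration(start_offset)),
    class = "count_image"
  )
}

#' Detector calibration factors
#'
#' Defaults reflect an alpha camera with 50% geometric efficiency, 23.8%
#' spatial pileup loss, and the Ac-225 frame-coincidence factor at 40 ms
#' frames (1.09). The implied absolute efficiency is
#' `geometric_efficiency * (1 - pileup_loss)` (38% at the defaults).
#'
#' @param geometric_efficiency Fraction in \[0, 1).
#' @param pileup_loss Fraction of events lost to spatial pileup, in \[0, 1).
#' @param frame_factor Frame-coincidence correction (>= 1).
#' @return A `calibration_factors` list (includes `absolute_efficiency`).
#' @export
calibration_factors <- function(geometric_efficiency = 0.5,
                                pileup_loss = 0.238,
                                frame_factor = frame_coincidence_factor(0.040, 0.032, 4)) {
  if (geometric_efficiency < 0 || geometric_efficiency >= 1 ||
      pileup_loss < 0 || pileup_loss >= 1) {
    abort("efficiency fractions must be in [0, 1)", class = "alphadose3d_domain_error")
  }
  if (frame_factor < 1) abort("frame_factor must be >= 1", class = "alphadose3d_domain_error")
  structure(
    list(geometric_efficiency = geometric_efficiency,
         pileup_loss = pileup_loss,
         frame_factor = frame_factor,
         absolute_efficiency = geometric_efficiency * (1 - pileup_loss)),
    class = "calibration_factors"
  )
}

#' Construct an activity image / volume
#'
#' @param activity Non-negative matrix (image) or 3D array (volume) of
#'   parent activity in Bq per voxel, referenced to sacrifice.
#' @param pixel_size_um In-plane pixel size (um).
#' @param slice_thickness_um Slice thickness (um).
#' @return An `activity_image`.
#' @export
activity_image <- function(activity, pixel_size_um, slice_thickness_um = 10) {
  activity <- as.matrix(activity)
  if (any(activity < 0)) abort("activity must be >= 0", class = "alphadose3d_domain_error")
  structure(
    list(activity = activity, pixel_size_um = pixel_size_um,
         slice_thickness_um = slice_thickness_um),
    class = "activity_image"
  )
}

#' @param voxel_dims_um Length-3 voxel dimensions (um).
#' @rdname activity_image
#' @export
activity_volume <- function(activity, voxel_dims_um) {
  stopifnot(length(dim(activity)) == 3, length(voxel_dims_um) == 3)
  if (any(activity < 0)) abort("activity must be >= 0", class = "alphadose3d_domain_error")
  structure(
    list(activity = activity, voxel_dims_um = as.numeric(voxel_dims_um)),
    class = "activity_volume"
  )
}

#' Convert a count image to a calibrated activity image
#'
#' Per-pixel parent activity
#' `counts * frame_factor / (alphas_per_chain * geometric_efficiency *
#' (1 - pileup_loss) * live_time)`, decay-corrected back to sacrifice by
#' the acquisition start offset using the parent half-life.
#'
#' @param img A `count_image`.
#' @param cal A `calibration_factors`.
#' @param chain A `decay_chain` (supplies alphas per chain decay and the
#'   parent half-life).
#' @return An `activity_image` (Bq of parent per pixel at sacrifice).
#' @export
counts_to_activity_image <- function(img, cal, chain = ac225_chain()) {
  stopifnot(inherits(img, "count_image"), inherits(cal, "calibration_factors"))
  if (img$live_time_s <= 0) abort("live_time must be > 0", class = "alphadose3d_domain_error")
  alphas <- attr(chain, "alphas_per_chain")
  act <- img$counts * cal$frame_factor /
    (alphas * cal$geometric_efficiency * (1 - cal$pileup_loss) * img$live_time_s)
  parent_hl <- chain$half_life_s[chain$name == attr(chain, "parent")]
  act <- decay_correct(act, img$start_offset_s, parent_hl)
  activity_image(act, img$pixel_size_um, img$slice_thickness_um)
}

#' Clone a measured slice into a convolution input volume
#'
#' The cloning method approximates the unmeasured 3D neighborhood of a thin
#' slice by stacking `n_clones` copies of it at the slice pitch, on the
#' assumption that adjacent slices are nearly identical.
#'
#' @param slice An `activity_image`.
#' @param n_clones Odd number of planes (the measured slice is central).
#' @param clone_thickness_um Plane pitch in um (defaults to the slice
#'   thickness).
#' @return An `activity_volume` of `n_clones` identical planes.
#' @export
clone_volume <- function(slice, n_clones = 21, clone_thickness_um = NULL) {
  stopifnot(inherits(slice, "activity_image"))
  if (n_clones < 1 || n_clones %% 2 == 0) {
    abort("n_clones must be odd and >= 1", class = "alphadose3d_contract_error")
  }
  thick <- clone_thickness_um %||% slice$slice_thickness_um
  d <- dim(slice$activity)
  vol <- array(slice$activity, dim = c(d, n_clones))
  activity_volume(vol, c(slice$pixel_size_um, slice$pixel_size_um, thick))
}

# Linear (zero-padded) 3D convolution via FFT; kernel must have odd dims.
.conv3d <- function(x, k) {
  dx <- dim(x); dk <- dim(k)
  stopifnot(all(dk %% 2 == 1))
  df <- dx + dk - 1
  dp <- vapply(df, function(s) nextn(s, factors = c(2, 3, 5)), numeric(1))
  xp <- array(0, dp); xp[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  kp <- array(0, dp); kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  full <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / prod(dp)
  off <- (dk - 1) / 2
  out <- full[off[1] + seq_len(dx[1]), off[2] + seq_len(dx[2]),
              off[3] + seq_len(dx[3]), drop = FALSE]
  array(out, dim = dx)
}

#' Convolve an activity volume with a dose-point kernel
#'
#' Linear 3D convolution with zero-padded boundaries (tissue in air/OCT:
#' escaping dose is lost), scaled from decays/s to Gy/h.
#'
#' @param vol An `activity_volume` (Bq per voxel).
#' @param kernel A voxelized `dose_point_kernel` whose `voxel_dims` match
#'   the volume's.
#' @param provenance Label recorded on the result.
#' @return A `dose_rate_volume` (Gy/h per voxel at the reference time).
#' @export
convolve_dose_rate <- function(vol, kernel, provenance = "stacked") {
  stopifnot(inherits(vol, "activity_volume"), inherits(kernel, "dose_point_kernel"))
  if (is.null(kernel$voxel_kernel)) abort("kernel is not voxelized")
  if (!isTRUE(all(abs(kernel$voxel_dims - vol$voxel_dims_um) < 1e-6))) {
    abort("kernel voxel dims do not match volume voxel dims",
          class = "alphadose3d_contract_error")
  }
  dr <- .conv3d(vol$activity, kernel$voxel_kernel) * 3600
  dr[dr < 0 & dr > -1e-12 * max(abs(dr))] <- 0 # FFT round-off
  structure(
    list(dose_rate = dr, voxel_dims_um = vol$voxel_dims_um,
         provenance = provenance),
    class = "dose_rate_volume"
  )
}

#' Extract one plane of a dose-rate volume as a dose-rate image
#'
#' @param drv A `dose_rate_volume`.
#' @param z Plane index; defaults to the central plane.
#' @return A `dose_rate_image` (matrix plus pixel size).
#' @export
extract_plane <- function(drv, z = NULL) {
  stopifnot(inherits(drv, "dose_rate_volume"))
  nz <- dim(drv$dose_rate)[3]
  z <- z %||% ((nz + 1) %/% 2)
  structure(
    list(dose_rate = drv$dose_rate[, , z], pixel_size_um = drv$voxel_dims_um[1],
         provenance = drv$provenance),
    class = "dose_rate_image"
  )
}

#' Cloning-method dose rate of a single measured slice
#'
#' Clones the slice ([clone_volume()]), convolves with the kernel, and
#' returns the central plane.
#'
#' @inheritParams clone_volume
#' @param kernel A voxelized `dose_point_kernel` (voxel z dimension must
#'   match the clone pitch).
#' @return A `dose_rate_image`.
#' @export
cloning_dose_rate <- function(slice, kernel, n_clones = 21,
                              clone_thickness_um = NULL) {
  vol <- clone_volume(slice, n_clones, clone_thickness_um)
  extract_plane(convolve_dose_rate(vol, kernel, provenance = "cloning"))
}

#' Sequential-method dose rate from consecutive measured slices
#'
#' Stacks registered consecutive slices at the slice pitch, convolves, and
#' returns the central plane — the reference method the cloning
#' approximation is validated against.
#'
#' @param slices List of >= 3 `activity_image`s of equal shape.
#' @param kernel A voxelized `dose_point_kernel`.
#' @return A `dose_rate_image` (provenance `"sequential"`).
#' @export
sequential_dose_rate <- function(slices, kernel) {
  if (length(slices) < 3) {
    abort("need >= 3 registered slices", class = "alphadose3d_contract_error")
  }
  shapes <- vapply(slices, function(s) paste(dim(s$activity), collapse = "x"), "")
  if (length(unique(shapes)) != 1) {
    abort("slice shapes differ", class = "alphadose3d_contract_error")
  }
  px <- slices[[1]]$pixel_size_um
  thick <- slices[[1]]$slice_thickness_um
  vol <- array(unlist(lapply(slices, function(s) s$activity)),
               dim = c(dim(slices[[1]]$activity), length(slices)))
  drv <- convolve_dose_rate(activity_volume(vol, c(px, px, thick)), kernel,
                            provenance = "sequential")
  extract_plane(drv)
}

#' Mean dose-rate error of the cloning method against the sequential method
#'
#' `|mean(cloning) - mean(sequential)| / mean(sequential) * 100`.
#'
#' @param cloning,sequential `dose_rate_image`s of the same shape.
#' @return Percent error (scalar).
#' @export
method_error <- function(cloning, sequential) {
  a <- if (inherits(cloning, "dose_rate_image")) cloning$dose_rate else cloning
  b <- if (inherits(sequential, "dose_rate_image")) sequential$dose_rate else sequential
  stopifnot(all(dim(a) == dim(b)))
  mb <- mean(b)
  if (mb == 0) abort("sequential mean is zero", class = "alphadose3d_domain_error")
  abs(mean(a) - mb) / mb * 100
}

#' Assemble sparsely sampled dose-rate slices into a 3D volume
#'
#' Slices measured every `z_pitch_um` are stacked in cut order; each
#' measured slice's dose rate represents its full z voxel, whose extent is
#' `z_pitch_um + slice_thickness_um` (e.g. 200 um sampling of 10 um slices
#' gives 210 um z voxels).
#'
#' @param slices List of >= 2 `dose_rate_image`s of equal shape.
#' @param z_pitch_um Sampling interval between slice positions (um).
#' @param slice_thickness_um Physical slice thickness (um).
#' @return A `dose_rate_volume` with anisotropic voxel dims.
#' @export
assemble_3d <- function(slices, z_pitch_um = 200, slice_thickness_um = 10) {
  if (length(slices) < 2) abort("need >= 2 slices", class = "alphadose3d_contract_error")
  shapes <- vapply(slices, function(s) paste(dim(s$dose_rate), collapse = "x"), "")
  if (length(unique(shapes)) != 1) {
    abort("slice shapes differ", class = "alphadose3d_contract_error")
  }
  px <- slices[[1]]$pixel_size_um
  vol <- array(unlist(lapply(slices, function(s) s$dose_rate)),
               dim = c(dim(slices[[1]]$dose_rate), length(slices)))
  structure(
    list(dose_rate = vol,
         voxel_dims_um = c(px, px, z_pitch_um + slice_thickness_um),
         provenance = "stacked"),
    class = "dose_rate_volume"
  )
}

#' Slice-sampling plan for 3D DAR
#'
#' Number of cut positions across a tissue extent at a sampling pitch, and
#' the total slices required given the slices needed per position (1 for
#' the cloning method, ~10 for the sequential method).
#'
#' @param tissue_extent_um Tissue extent along the cut axis (um).
#' @param sampling_pitch_um Interval between sampled positions (um).
#' @param slices_per_position Slices to prepare per position.
#' @return A tibble with `positions` and `total_slices`.
#' @examples
#' sampling_plan(5000, 200, 1)   # 25 slices
#' sampling_plan(5000, 200, 10)  # 250 slices
#' sampling_plan(5000, 10, 1)    # 500 sections
#' @export
sampling_plan <- function(tissue_extent_um, sampling_pitch_um,
                          slices_per_position = 1) {
  if (tissue_extent_um <= 0 || sampling_pitch_um <= 0 || slices_per_position <= 0) {
    abort("all inputs must be positive", class = "alphadose3d_domain_error")
  }
  positions <- floor(tissue_extent_um / sampling_pitch_um)
  if (positions == 0) {
    warn("sampling pitch exceeds tissue extent: zero positions")
  }
  tibble(positions = positions, total_slices = positions * slices_per_position)
}

#' Gamma-index comparison of two dose distributions
#'
#' For each reference voxel `i`, `gamma_i` is the minimum over evaluated
#' voxels `j` in a search neighborhood of
#' `sqrt((D_e(j) - D_r(i))^2 / (dose_tol * D_norm)^2 + d(i,j)^2 / dist_tol^2)`,
#' with `D_norm` the local reference dose (local normalization) or the
#' reference maximum (global). A voxel passes at `gamma <= 1`. The search is
#' restricted to a radius of `search_radius_factor * dist_tol` (set to
#' `Inf` for an exhaustive search).
#'
#' @param ref,eval `dose_rate_image`s (or matrices, with `pixel_size_um`
#'   supplied) of identical shape and pixel size.
#' @param dose_tol Dose-difference tolerance as a fraction (default 0.10).
#' @param dist_tol Distance-to-agreement tolerance in um (default 117, i.e.
#'   three 39-um pixels).
#' @param normalization `"local"` or `"global"`.
#' @param floor Low-dose threshold as a fraction of the reference maximum;
#'   voxels below it are excluded from the pass rate (default 0).
#' @param search_radius_factor Neighborhood radius in units of `dist_tol`.
#' @param pixel_size_um Pixel size when matrices are supplied.
#' @return A `gamma_result`: `gamma_map`, `pass_rate` (fraction with
#'   `gamma <= 1`), `pass_rate_strict` (`gamma < 1`), `n_evaluated`,
#'   `criteria`.
#' @export
gamma_index <- function(ref, eval, dose_tol = 0.10, dist_tol = 117,
                        normalization = c("local", "global"), floor = 0,
                        search_radius_factor = 3, pixel_size_um = NULL) {
  normalization <- match.arg(normalization)
  if (dose_tol <= 0 || dist_tol <= 0) {
    abort("tolerances must be > 0", class = "alphadose3d_domain_error")
  }
  if (inherits(ref, "dose_rate_image")) {
    pixel_size_um <- pixel_size_um %||% ref$pixel_size_um
    ref <- ref$dose_rate
  }
  if (inherits(eval, "dose_rate_image")) eval <- eval$dose_rate
  if (is.null(pixel_size_um)) abort("pixel_size_um required for matrix input")
  ref <- as.matrix(ref); eval <- as.matrix(eval)
  if (!all(dim(ref) == dim(eval))) {
    abort("images must have the same shape", class = "alphadose3d_contract_error")
  }
  nr <- nrow(ref); nc <- ncol(ref)
  rmax <- max(ref)
  dnorm_map <- if (normalization == "local") ref else array(rmax, dim(ref))

  radius <- search_radius_factor * dist_tol
  max_px <- if (is.finite(radius)) floor(radius / pixel_size_um) else max(nr, nc)
  offs <- expand.grid(dx = -max_px:max_px, dy = -max_px:max_px)
  offs$dist <- pixel_size_um * sqrt(offs$dx^2 + offs$dy^2)
  if (is.finite(radius)) offs <- offs[offs$dist <= radius, ]

  g2 <- array(Inf, dim(ref))
  denom2 <- (dose_tol * dnorm_map)^2
  for (o in seq_len(nrow(offs))) {
    dx <- offs$dx[o]; dy <- offs$dy[o]
    rlo <- max(1, 1 - dx); rhi <- min(nr, nr - dx)
    clo <- max(1, 1 - dy); chi <- min(nc, nc - dy)
    if (rlo > rhi || clo > chi) next
    ri <- rlo:rhi; ci <- clo:chi
    num <- (eval[ri + dx, ci + dy, drop = FALSE] - ref[ri, ci, drop = FALSE])^2
    den <- denom2[ri, ci, drop = FALSE]
    dterm <- num / den
    dterm[den == 0] <- ifelse(num[den == 0] == 0, 0, Inf) # zero-dose voxels
    dd <- dterm + (offs$dist[o] / dist_tol)^2
    g2[ri, ci] <- pmin(g2[ri, ci], dd)
  }
  gamma_map <- sqrt(g2)
  include <- ref >= floor * rmax
  if (!any(include)) {
    abort("all voxels below the low-dose floor", class = "alphadose3d_empty_evaluation_error")
  }
  structure(
    list(
      gamma_map = gamma_map,
      pass_rate = mean(gamma_map[include] <= 1),
      pass_rate_strict = mean(gamma_map[include] < 1),
      n_evaluated = sum(include),
      criteria = list(dose_tol = dose_tol, dist_tol_um = dist_tol,
                      normalization = normalization, floor = floor,
                      search_radius_factor = search_radius_factor,
                      pixel_size_um = pixel_size_um)
    ),
    class = "gamma_result"
  )
}
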