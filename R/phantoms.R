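# Synthetic tissue phantoms and measurement simulators: every input the
# analysis pipeline consumes can be generated here with a fixed seed.
# Geometry and compartment statistics are exact before noise; counting
# noise is Poisson; inter-subject uptake variability is lognormal.

#' Phantom specification
#'
#' @param shape Voxel counts (length 3).
#' @param voxel_dims_um Voxel dimensions in um (length 3).
#' @param total_activity_Bq Total parent activity distributed over the
#'   phantom.
#' @param necrotic_fraction Necrotic-core volume fraction of the tumor, in
#'   \[0, 1).
#' @param uptake Per-compartment relative uptake. Tumors: `c(rim, core)`;
#'   kidneys: `c(cortex, ISOM/OSOM, IM/Pa, V/Pe)` (defaults follow
#'   measured 24 h compartment dose-rate ratios 1 / 0.50 / 0.88 / 1.19).
#' @param cell_density Cells per voxel by compartment (tumors:
#'   `c(rim, core)`).
#' @param seed Integer seed; fixed seed gives bit-reproducible phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48, 48, 48),
                         voxel_dims_um = c(39, 39, 39),
                         total_activity_Bq = 5,
                         necrotic_fraction = 0.3,
                         uptake = NULL,
                         cell_density = c(rim = 500, core = 10),
                         seed = 1L) {
  if (necrotic_fraction < 0 || necrotic_fraction >= 1) {
    abort("necrotic_fraction must be in [0, 1)", class = "alphadose3d_domain_error")
  }
  if (!is.null(uptake) && any(uptake < 0)) {
    abort("uptakes must be >= 0", class = "alphadose3d_domain_error")
  }
  structure(
    list(shape = shape, voxel_dims_um = voxel_dims_um,
         total_activity_Bq = total_activity_Bq,
         necrotic_fraction = necrotic_fraction,
         uptake = uptake, cell_density = cell_density, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# normalized ellipsoid radius^2 for every voxel center
.ellipsoid_r2 <- function(shape, semi_axes_vox) {
  cx <- (shape + 1) / 2
  x <- ((seq_len(shape[1]) - cx[1]) / semi_axes_vox[1])^2
  y <- ((seq_len(shape[2]) - cx[2]) / semi_axes_vox[2])^2
  z <- ((seq_len(shape[3]) - cx[3]) / semi_axes_vox[3])^2
  outer(outer(x, y, `+`), z, `+`)
}

#' Ellipsoidal tumor phantom with a necrotic core
#'
#' An ellipsoidal tumor filling ~80% of the grid per axis, with an inner
#' necrotic core whose volume fraction of the tumor equals
#' `necrotic_fraction` (core semi-axes scale as the cube root). The viable
#' rim carries high uptake and cell density; the core low uptake and few
#' cells. Pre-noise compartment means are exact; activity sums to
#' `total_activity_Bq`.
#'
#' @param spec A [phantom_spec()]. `uptake` defaults to
#'   `c(rim = 1, core = 0.1)`.
#' @return A list with `activity` (`activity_volume`), `cells` (3D array of
#'   cells per voxel), `mask` (a [region_mask()]: 1 = rim, 2 = core).
#' @export
tumor_phantom <- function(spec = phantom_spec()) {
  uptake <- spec$uptake %||% c(rim = 1, core = 0.1)
  stopifnot(length(uptake) == 2)
  semi <- spec$shape * 0.4
  r2 <- .ellipsoid_r2(spec$shape, semi)
  tumor <- r2 <= 1
  core_scale <- spec$necrotic_fraction^(1 / 3)
  core <- if (core_scale > 0) .ellipsoid_r2(spec$shape, semi * core_scale) <= 1 else
    array(FALSE, spec$shape)
  if (sum(core) > sum(tumor)) {
    abort("necrotic core larger than tumor", class = "alphadose3d_contract_error")
  }
  labels <- array(0L, spec$shape)
  labels[tumor] <- 1L
  labels[core] <- 2L
  rel <- array(0, spec$shape)
  rel[labels == 1L] <- uptake[[1]]
  rel[labels == 2L] <- uptake[[2]]
  act <- rel * spec$total_activity_Bq / sum(rel)
  cells <- array(0, spec$shape)
  cells[labels == 1L] <- spec$cell_density[[1]]
  cells[labels == 2L] <- spec$cell_density[[2]]
  list(
    activity = activity_volume(act, spec$voxel_dims_um),
    cells = cells,
    mask = region_mask(labels, c("1" = "rim", "2" = "core"))
  )
}

#' Four-compartment kidney phantom
#'
#' Concentric ellipsoidal compartments (cortex shell, ISOM/OSOM shell,
#' IM/Pa core) plus a vasculature/pelvis wedge reaching the center,
#' emulating a kidney cross-section stack. Labels partition the organ;
#' compartment-mean activities are exactly proportional to the uptake
#' ratios before noise.
#'
#' @param spec A [phantom_spec()]. `uptake` defaults to
#'   `c(cortex = 1, "ISOM/OSOM" = 0.50, "IM/Pa" = 0.88, "V/Pe" = 1.19)`.
#' @return A list with `activity` (`activity_volume`) and `mask`
#'   (labels 1-4 with the legend above).
#' @export
kidney_phantom <- function(spec = phantom_spec()) {
  uptake <- spec$uptake %||%
    c(cortex = 1, "ISOM/OSOM" = 0.50, "IM/Pa" = 0.88, "V/Pe" = 1.19)
  stopifnot(length(uptake) == 4)
  semi <- spec$shape * 0.42
  r2 <- .ellipsoid_r2(spec$shape, semi)
  organ <- r2 <= 1
  labels <- array(0L, spec$shape)
  labels[r2 <= 1] <- 1L                 # cortex (outer shell)
  labels[r2 <= 0.55] <- 2L              # ISOM/OSOM
  labels[r2 <= 0.25] <- 3L              # IM/Pa
  # vasculature / pelvis: a wedge from the center toward +x
  cx <- (spec$shape + 1) / 2
  xi <- slice.index(labels, 1); yi <- slice.index(labels, 2)
  wedge <- organ & xi > cx[1] & abs(yi - cx[2]) <= pmax(1, spec$shape[2] * 0.06)
  labels[wedge] <- 4L
  rel <- array(0, spec$shape)
  for (k in 1:4) rel[labels == k] <- uptake[[k]]
  act <- rel * spec$total_activity_Bq / sum(rel)
  legend <- c("1" = "cortex", "2" = "ISOM/OSOM", "3" = "IM/Pa", "4" = "V/Pe")
  list(
    activity = activity_volume(act, spec$voxel_dims_um),
    mask = region_mask(labels, legend)
  )
}

#' Simulate a count image from a known activity image
#'
#' Poisson draws with mean
#' `activity * alphas_per_chain * geometric_efficiency * (1 - pileup_loss)
#'  * live_time / frame_factor` — the inverse of
#' [counts_to_activity_image()].
#'
#' @param activity An `activity_image` (Bq per pixel at sacrifice).
#' @param cal A [calibration_factors()].
#' @param live_time Acquisition live time (seconds or unit string).
#' @param chain A `decay_chain`.
#' @param seed Integer seed.
#' @return A `count_image` (with zero start offset: the simulated counts
#'   are already referenced to sacrifice).
#' @export
simulate_counts <- function(activity, cal, live_time = 86400,
                            chain = ac225_chain(), seed = 1L) {
  stopifnot(inherits(activity, "activity_image"))
  live_time <- parse_duration(live_time)
  alphas <- attr(chain, "alphas_per_chain")
  mu <- activity$activity * alphas * cal$geometric_efficiency *
    (1 - cal$pileup_loss) * live_time / cal$frame_factor
  counts <- .with_seed(seed, matrix(rpois(length(mu), mu), nrow(mu)))
  count_image(counts, activity$pixel_size_um, activity$slice_thickness_um,
              live_time = live_time, start_offset = 0)
}

#' Two-fold dilution series of droplet standards
#'
#' @param stock_Bq_uL Stock concentration (Bq/uL).
#' @param n_dilutions Number of successive two-fold dilutions.
#' @param droplet_volume_uL Droplet volume (uL).
#' @return A tibble with `dilution` (0 = stock), `concentration_Bq_uL`,
#'   `droplet_Bq`.
#' @examples
#' dilution_series(185, 5, 2)
#' @export
dilution_series <- function(stock_Bq_uL = 185, n_dilutions = 5,
                            droplet_volume_uL = 2) {
  if (stock_Bq_uL <= 0 || droplet_volume_uL <= 0 || n_dilutions < 0) {
    abort("inputs must be positive", class = "alphadose3d_domain_error")
  }
  k <- 0:n_dilutions
  conc <- stock_Bq_uL / 2^k
  tibble(dilution = k, concentration_Bq_uL = conc,
         droplet_Bq = conc * droplet_volume_uL)
}

#' Simulate a post-sacrifice activity-ratio series
#'
#' Forward ratio-decay values with multiplicative Gaussian counting noise
#' of coefficient of variation `counting_error_cv`.
#'
#' @param r0 True initial daughter/parent ratio.
#' @param times_s Measurement times post-sacrifice (strictly increasing, s).
#' @param counting_error_cv Multiplicative noise CV (0 = exact).
#' @param chain A `decay_chain`.
#' @param seed Integer seed.
#' @return A ratio-series tibble (`time_s`, `ratio`, `sigma`).
#' @export
simulate_ratio_series <- function(r0, times_s, counting_error_cv = 0.02,
                                  chain = ac225_chain(), seed = 1L) {
  if (any(diff(times_s) <= 0)) {
    abort("times must be strictly increasing", class = "alphadose3d_domain_error")
  }
  truth <- ratio_at_time(r0, times_s, chain)
  noisy <- .with_seed(seed, truth * (1 + counting_error_cv * rnorm(length(truth))))
  tibble(time_s = times_s, ratio = pmax(noisy, 1e-12),
         sigma = counting_error_cv * truth)
}

#' Simulate a biodistribution cohort for TRC fitting
#'
#' Each subject scales a shared bi-exponential dose-rate curve by a
#' lognormal factor with unit mean and the stated inter-subject CV; one
#' point per subject per time.
#'
#' @param trc_params List with `amplitudes` (mGy/h) and `rates` (1/h).
#' @param times_h Measurement times post-injection (h).
#' @param n_subjects Subjects per cohort.
#' @param inter_subject_cv Lognormal CV of subject uptake (default 0.3).
#' @param component Label recorded on the points.
#' @param seed Integer seed.
#' @return A tibble with `subject_id`, `time_h`, `dose_rate_mGy_h`,
#'   `component`.
#' @export
simulate_biod_cohort <- function(trc_params, times_h, n_subjects = 17,
                                 inter_subject_cv = 0.3,
                                 component = "Ac225", seed = 1L) {
  stopifnot(n_subjects >= 1)
  sdlog <- sqrt(log(1 + inter_subject_cv^2))
  .with_seed(seed, {
    scale <- rlnorm(n_subjects, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      rate <- trc_params$amplitudes[1] * exp(-trc_params$rates[1] * times_h)
      if (length(trc_params$amplitudes) > 1) {
        rate <- rate + trc_params$amplitudes[2] * exp(-trc_params$rates[2] * times_h)
      }
      tibble(subject_id = sprintf("S%02d", s), time_h = times_h,
             dose_rate_mGy_h = rate * scale[s], component = component)
    })
  })
}

#' Simulate a gamma spectrum with a photopeak on a linear background
#'
#' Poisson counts around `area * gauss(center, width) + background`
#' (background linear in energy), on a uniform keV binning.
#'
#' @param bin_edges Energy bin edges (keV).
#' @param area True photopeak area (counts).
#' @param center,width Gaussian photopeak parameters (keV).
#' @param bg_slope,bg_intercept Linear background (counts per bin).
#' @param live_time Counting time (s).
#' @param poisson Add Poisson noise (default `TRUE`).
#' @param seed Integer seed.
#' @return An `energy_spectrum`.
#' @export
simulate_spectrum <- function(bin_edges, area, center, width,
                              bg_slope = 0, bg_intercept = 20,
                              live_time = 60, poisson = TRUE, seed = 1L) {
  mid <- (head(bin_edges, -1) + tail(bin_edges, -1)) / 2
  dx <- diff(bin_edges)
  mu <- area * dnorm(mid, center, width) * dx + bg_slope * mid + bg_intercept
  mu <- pmax(mu, 0)
  counts <- if (poisson) .with_seed(seed, rpois(length(mu), mu)) else mu
  energy_spectrum(bin_edges, counts, live_time)
}

# Evaluate expr with a local RNG seed, restoring the global state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
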