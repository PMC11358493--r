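# Gamma-counter energy-window quantification: Gaussian-plus-linear window
# fits, branching/efficiency corrections and known-activity efficiency
# calibration. Default analysis windows are 168-268 keV (Fr-221) and
# 370-510 keV (Bi-213); droplet-calibration windows 175-250 and 385-490 keV.

#' Construct an energy spectrum
#'
#' @param bin_edges Strictly increasing vector of bin edges (keV), length
#'   `length(counts) + 1`.
#' @param counts Non-negative counts per bin.
#' @param live_time Active counting time in seconds.
#' @return An `energy_spectrum` object (list with `bin_edges`, `counts`,
#'   `live_time_s`, `mid` bin centers).
#' @export
energy_spectrum <- function(bin_edges, counts, live_time) {
  live_time <- parse_duration(live_time)
  if (any(diff(bin_edges) <= 0)) {
    abort("bin edges must be strictly increasing", class = "alphadose3d_domain_error")
  }
  if (length(bin_edges) != length(counts) + 1) {
    abort("length(bin_edges) must equal length(counts) + 1")
  }
  if (any(counts < 0)) abort("counts must be >= 0", class = "alphadose3d_domain_error")
  if (live_time <= 0) abort("live_time must be > 0", class = "alphadose3d_domain_error")
  structure(
    list(bin_edges = as.numeric(bin_edges), counts = as.numeric(counts),
         live_time_s = live_time,
         mid = (head(bin_edges, -1) + tail(bin_edges, -1)) / 2),
    class = "energy_spectrum"
  )
}

#' Read a spectrum CSV (`bin_lo_keV`, `bin_hi_keV`, `counts`)
#'
#' @param path CSV path. Live time is taken from `live_time_s` (either a
#'   column, constant, or a JSON sidecar `<path>.json` with field
#'   `live_time_s`).
#' @return An `energy_spectrum`.
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("bin_lo_keV", "bin_hi_keV", "counts") %in% names(df)))
  lt <- if ("live_time_s" %in% names(df)) {
    df$live_time_s[1]
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) abort("no live_time_s column or JSON sidecar")
    jsonlite::read_json(sidecar)$live_time_s
  }
  energy_spectrum(c(df$bin_lo_keV, df$bin_hi_keV[nrow(df)]), df$counts, lt)
}

#' Fit a Gaussian photopeak on a linear background within an energy window
#'
#' Least-squares fit of `counts ~ area * gauss(center, width) + slope * E +
#' intercept` over the bins inside `window`, the standard net-count model
#' for a single photopeak over ambient background / down-scatter. The net
#' counts are the fitted Gaussian area, clamped at zero (with a flag) since
#' activities are physical.
#'
#' @param spectrum An `energy_spectrum`.
#' @param window Numeric length-2, keV range (within the spectrum support).
#' @return A `window_fit` list: `net_counts`, `net_sigma`,
#'   `background_counts`, `gaussian_params` (center, width, area),
#'   `linear_params` (slope, intercept), `clamped`, `window`,
#'   `residuals`, `bins` (tibble of the fitted window).
#' @export
fit_window <- function(spectrum, window) {
  stopifnot(inherits(spectrum, "energy_spectrum"), length(window) == 2)
  window <- sort(as.numeric(window))
  if (window[1] < min(spectrum$bin_edges) || window[2] > max(spectrum$bin_edges)) {
    abort("window outside spectrum support", class = "alphadose3d_domain_error")
  }
  sel <- spectrum$mid >= window[1] & spectrum$mid <= window[2]
  if (sum(sel) < 6) abort("need >= 6 bins in window", class = "alphadose3d_design_error")
  x <- spectrum$mid[sel]
  y <- spectrum$counts[sel]
  dx <- diff(spectrum$bin_edges)[sel]

  # Initialization: center = window midpoint, width = window/6, area from
  # total minus a linear interpolation between the endpoint bins.
  c0 <- mean(window)
  s0 <- diff(window) / 6
  endpoints <- stats::approx(x[c(1, length(x))], y[c(1, length(x))], xout = x)$y
  a0 <- max(sum(y - endpoints), sum(y) * 0.1)
  sl0 <- (y[length(y)] - y[1]) / (x[length(x)] - x[1])
  in0 <- y[1] - sl0 * x[1]

  model <- function(p) p[1] * dnorm(x, p[2], p[3]) * dx + p[4] * x + p[5]
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(area = a0, center = c0, width = s0, slope = sl0, intercept = in0),
      lower = c(0, window[1], diff(window) / 100, -Inf, -Inf),
      upper = c(Inf, window[2], diff(window), Inf, Inf),
      fn = function(p) y - model(p),
      control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000)
    ),
    error = function(e) {
      abort(paste0("window fit failed to converge: ", conditionMessage(e)),
            class = "alphadose3d_fit_error")
    }
  )
  if (!fit$info %in% 1:4) {
    abort(paste0("window fit failed to converge: ", fit$message),
          class = "alphadose3d_fit_error",
          residuals = fit$fvec)
  }
  p <- coef(fit)
  area <- unname(p["area"])
  clamped <- FALSE
  if (area <= 0) { # at the non-negativity bound
    area <- 0
    clamped <- TRUE
  }
  gauss <- area * dnorm(x, p["center"], p["width"]) * dx
  linear <- p["slope"] * x + p["intercept"]
  se <- tryCatch(summary(fit)$coefficients["area", "Std. Error"],
                 error = function(e) NA_real_)
  structure(
    list(
      net_counts = area,
      net_sigma = unname(se),
      background_counts = sum(linear),
      gaussian_params = c(center = unname(p["center"]), width = unname(p["width"]),
                          area = area),
      linear_params = c(slope = unname(p["slope"]), intercept = unname(p["intercept"])),
      clamped = clamped,
      window = window,
      residuals = y - (gauss + linear),
      bins = tibble(energy_keV = x, counts = y, gaussian = gauss, linear = linear)
    ),
    class = "window_fit"
  )
}

#' Convert net counts in a window to activity
#'
#' `activity = net / (branching * efficiency * live_time)`, with Poisson
#' 1-sigma propagated from the net counts (or a supplied `net_sigma`).
#'
#' @param net Net counts (>= 0).
#' @param branching Photon branching ratio, in (0, 1].
#' @param efficiency Energy-dependent detector efficiency, in (0, 1].
#' @param live_time Active counting time in seconds (> 0).
#' @param net_sigma Optional 1-sigma on `net`; defaults to `sqrt(net)`.
#' @return A list with `activity_Bq` and `sigma_Bq`.
#' @export
counts_to_activity <- function(net, branching, efficiency, live_time,
                               net_sigma = NULL) {
  live_time <- parse_duration(live_time)
  if (branching <= 0 || branching > 1 || efficiency <= 0 || efficiency > 1) {
    abort("branching and efficiency must be in (0, 1]",
          class = "alphadose3d_domain_error")
  }
  if (live_time <= 0) abort("live_time must be > 0", class = "alphadose3d_domain_error")
  denom <- branching * efficiency * live_time
  sig <- (net_sigma %||% sqrt(pmax(net, 0))) / denom
  list(activity_Bq = net / denom, sigma_Bq = sig)
}

#' Calibrate detector efficiency from known-activity standards
#'
#' Least-squares proportionality fit of measured net counts against the
#' expected counts `branching * live_time * activity` over a dilution
#' series: `efficiency = sum(x y) / sum(x^2)` with `x` the expected counts.
#'
#' @param known_activities Vector of standard activities (Bq).
#' @param measured_nets Vector of measured net counts (same length).
#' @param branching Photon branching ratio in (0, 1].
#' @param live_time Counting time in seconds (> 0).
#' @return A list with `efficiency` and `sigma` (1-sigma from residual
#'   scatter; Poisson-based for a single point).
#' @export
calibrate_efficiency <- function(known_activities, measured_nets,
                                 branching, live_time) {
  live_time <- parse_duration(live_time)
  stopifnot(length(known_activities) == length(measured_nets),
            length(known_activities) >= 1)
  if (all(known_activities == 0)) {
    abort("all-zero activities: degenerate design", class = "alphadose3d_design_error")
  }
  x <- branching * live_time * known_activities
  y <- measured_nets
  eff <- sum(x * y) / sum(x^2)
  n <- length(x)
  sig <- if (n > 1) {
    sqrt(sum((y - eff * x)^2) / (n - 1) / sum(x^2))
  } else {
    sqrt(pmax(y, 0)) / x # Poisson on the single measurement
  }
  list(efficiency = eff, sigma = unname(sig))
}
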