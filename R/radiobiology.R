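# Linear-quadratic survival, voxel/slice/volume tumor control probability,
# and injected-activity de-escalation prediction.

#' Radiosensitivity parameters for the linear-quadratic model
#'
#' For high-LET alpha emissions `alpha >> beta`; the default is the pure
#' linear model with `alpha = 1.8` per Gy (an in vitro survival-assay value
#' for the targeted compound) and `beta = 0`.
#'
#' @param alpha Linear coefficient, 1/Gy (> 0).
#' @param beta Quadratic coefficient, 1/Gy^2 (>= 0).
#' @return A `radiosensitivity` list.
#' @export
radiosensitivity <- function(alpha = 1.8, beta = 0) {
  if (alpha <= 0 || beta < 0) {
    abort("alpha must be > 0 and beta >= 0", class = "alphadose3d_domain_error")
  }
  structure(list(alpha = alpha, beta = beta), class = "radiosensitivity")
}

#' Linear-quadratic surviving fraction
#'
#' `S(D) = exp(-alpha D - beta D^2)`.
#'
#' @param D Absorbed dose in Gy (vectorised, >= 0).
#' @param params A [radiosensitivity()].
#' @return Surviving fraction in (0, 1].
#' @export
survival_fraction <- function(D, params = radiosensitivity()) {
  if (any(D < 0)) abort("dose must be >= 0", class = "alphadose3d_domain_error")
  exp(-params$alpha * D - params$beta * D^2)
}

#' Voxel control probability
#'
#' The probability that none of the `n` clonogenic cells in a voxel
#' receiving uniform dose `D` survive: `VCP = exp(-n S(D))` (Poisson
#' statistics of surviving cells).
#'
#' @param n Cells in the voxel (non-negative real; vectorised).
#' @param D Voxel dose in Gy (vectorised).
#' @param params A [radiosensitivity()].
#' @return Probability in (0, 1].
#' @export
voxel_control_probability <- function(n, D, params = radiosensitivity()) {
  if (any(n < 0)) abort("cell counts must be >= 0", class = "alphadose3d_domain_error")
  exp(-n * survival_fraction(D, params))
}

#' Tumor control probability over a dose volume
#'
#' Per-voxel VCPs are multiplied within each slice and across slices:
#' `TCP = prod_i VCP(D_i)`. To reduce sensitivity to registration error at
#' tissue edges, a 5x5 erosion of the `n > 0` contour can exclude the edge
#' band from the products. Voxels with `VCP < underdose_threshold` (and
#' `n > 0`) are flagged as underdosed.
#'
#' @param dose_map 3D array (or matrix for a single slice) of voxel dose in
#'   Gy, or a `dose_volume` (its central `dose` is used).
#' @param cell_map Array of clonogenic cells per voxel, same shape.
#' @param params A [radiosensitivity()].
#' @param erosion Apply the 5x5 edge erosion (default `TRUE`).
#' @param erosion_px Side of the square erosion structuring element.
#' @param underdose_threshold VCP threshold for the underdosed mask
#'   (default 0.95).
#' @return A `tcp_result`: `vcp_map`, `included` (logical array entering
#'   the products), `slice_tcp` (tibble: `slice`, `tcp`, `n_voxels`,
#'   `mean_dose_Gy`), `volume_tcp`, `mean_slice_tcp`, `min_slice_tcp`,
#'   `underdosed_mask`.
#' @export
tcp <- function(dose_map, cell_map, params = radiosensitivity(),
                erosion = TRUE, erosion_px = 5, underdose_threshold = 0.95) {
  if (inherits(dose_map, "dose_volume")) dose_map <- dose_map$dose
  if (is.matrix(dose_map)) dose_map <- array(dose_map, c(dim(dose_map), 1))
  if (is.matrix(cell_map)) cell_map <- array(cell_map, c(dim(cell_map), 1))
  if (!all(dim(dose_map) == dim(cell_map))) {
    abort("dose and cell maps must have the same shape",
          class = "alphadose3d_contract_error")
  }
  if (any(cell_map < 0)) abort("cell counts must be >= 0",
                               class = "alphadose3d_domain_error")
  nz <- dim(dose_map)[3]
  s <- survival_fraction(dose_map, params)
  vcp <- exp(-cell_map * s)
  included <- array(TRUE, dim(dose_map))
  if (erosion) {
    for (z in seq_len(nz)) {
      included[, , z] <- erode_positive_contour(cell_map[, , z] > 0,
                                                erosion_px = erosion_px) > 0
    }
    # voxels with no cells contribute VCP = 1 regardless; keep them out of
    # the product bookkeeping for clarity
    included <- included & cell_map > 0
  } else {
    included <- cell_map > 0
  }
  slice_tcp <- purrr::map_dfr(seq_len(nz), function(z) {
    inc <- included[, , z]
    log_tcp <- sum(-cell_map[, , z][inc] * s[, , z][inc])
    tibble(
      slice = z,
      tcp = exp(log_tcp),
      n_voxels = sum(inc),
      mean_dose_Gy = if (any(inc)) mean(dose_map[, , z][inc]) else NA_real_
    )
  })
  structure(
    list(
      vcp_map = vcp, included = included, slice_tcp = slice_tcp,
      volume_tcp = prod(slice_tcp$tcp),
      mean_slice_tcp = mean(slice_tcp$tcp),
      min_slice_tcp = min(slice_tcp$tcp),
      underdosed_mask = vcp < underdose_threshold & cell_map > 0,
      params = params
    ),
    class = "tcp_result"
  )
}

#' @export
tidy.tcp_result <- function(x, ...) x$slice_tcp

#' @export
glance.tcp_result <- function(x, ...) {
  tibble(volume_tcp = x$volume_tcp, mean_slice_tcp = x$mean_slice_tcp,
         min_slice_tcp = x$min_slice_tcp, n_slices = nrow(x$slice_tcp),
         n_underdosed = sum(x$underdosed_mask))
}

#' Injected-activity de-escalation curves
#'
#' Assumes dose scales linearly with injected activity (IA) and preserves
#' the spatial distribution: for each IA on the grid, all voxel doses are
#' scaled by `IA / reference_ia`, TCP metrics are recomputed, and the
#' kidney dose scales linearly.
#'
#' @param dose_map,cell_map As in [tcp()] (doses at `reference_ia`).
#' @param kidney_dose_Gy Organ-mean kidney dose at `reference_ia`.
#' @param ia_grid_kBq Injected activities to evaluate (kBq).
#' @param reference_ia_kBq IA at which `dose_map` was measured.
#' @param params A [radiosensitivity()].
#' @param ... Passed to [tcp()] (e.g. `erosion`).
#' @return A `deescalation_curves` tibble: `ia_kBq`, `mean_slice_tcp`,
#'   `volume_tcp`, `min_slice_tcp`, `kidney_dose_Gy`; inputs kept as
#'   attributes so the curve can be refined at arbitrary IA.
#' @export
de_escalation <- function(dose_map, cell_map, kidney_dose_Gy,
                          ia_grid_kBq = seq(0, 18.5, by = 0.5),
                          reference_ia_kBq = 18.5,
                          params = radiosensitivity(), ...) {
  if (reference_ia_kBq <= 0) abort("reference IA must be > 0",
                                   class = "alphadose3d_domain_error")
  if (any(ia_grid_kBq < 0)) abort("IA grid must be >= 0",
                                  class = "alphadose3d_domain_error")
  if (inherits(dose_map, "dose_volume")) dose_map <- dose_map$dose
  rows <- purrr::map_dfr(ia_grid_kBq, function(ia) {
    f <- ia / reference_ia_kBq
    r <- tcp(dose_map * f, cell_map, params, ...)
    tibble(ia_kBq = ia, mean_slice_tcp = r$mean_slice_tcp,
           volume_tcp = r$volume_tcp, min_slice_tcp = r$min_slice_tcp,
           kidney_dose_Gy = kidney_dose_Gy * f)
  })
  structure(rows,
            dose_map = dose_map, cell_map = cell_map,
            kidney_dose_Gy = kidney_dose_Gy,
            reference_ia_kBq = reference_ia_kBq, params = params,
            tcp_args = list(...),
            class = c("deescalation_curves", class(rows)))
}

#' Smallest injected activity achieving a target TCP
#'
#' Bisects the (monotone) TCP-vs-IA relation of a [de_escalation()] result
#' to 0.1 kBq resolution, recomputing TCP exactly at each trial IA.
#'
#' @param curves A `deescalation_curves`.
#' @param target_tcp Target TCP in (0, 1).
#' @param metric `"mean_slice_tcp"` (default) or `"volume_tcp"` or
#'   `"min_slice_tcp"`.
#' @param resolution_kBq Bisection resolution (default 0.1).
#' @return A list with `ia_kBq` (NA if not achieved), `achieved`,
#'   `tcp_at_ia`.
#' @export
ia_for_tcp <- function(curves, target_tcp,
                       metric = c("mean_slice_tcp", "volume_tcp", "min_slice_tcp"),
                       resolution_kBq = 0.1) {
  metric <- match.arg(metric)
  if (target_tcp <= 0) {
    return(list(ia_kBq = min(curves$ia_kBq), achieved = TRUE,
                tcp_at_ia = curves[[metric]][which.min(curves$ia_kBq)]))
  }
  if (target_tcp >= 1) abort("target TCP must be in (0, 1)",
                             class = "alphadose3d_domain_error")
  dose_map <- attr(curves, "dose_map"); cell_map <- attr(curves, "cell_map")
  ref <- attr(curves, "reference_ia_kBq"); params <- attr(curves, "params")
  args <- attr(curves, "tcp_args")
  tcp_at <- function(ia) {
    r <- do.call(tcp, c(list(dose_map * ia / ref, cell_map, params), args))
    switch(metric, mean_slice_tcp = r$mean_slice_tcp,
           volume_tcp = r$volume_tcp, min_slice_tcp = r$min_slice_tcp)
  }
  hi <- max(curves$ia_kBq)
  if (tcp_at(hi) < target_tcp) {
    return(list(ia_kBq = NA_real_, achieved = FALSE, tcp_at_ia = tcp_at(hi)))
  }
  lo <- min(curves$ia_kBq)
  if (tcp_at(lo) >= target_tcp) {
    return(list(ia_kBq = lo, achieved = TRUE, tcp_at_ia = tcp_at(lo)))
  }
  while (hi - lo > resolution_kBq / 2) {
    mid <- (hi + lo) / 2
    if (tcp_at(mid) >= target_tcp) hi <- mid else lo <- mid
  }
  ia <- round(hi / resolution_kBq) * resolution_kBq
  list(ia_kBq = ia, achieved = TRUE, tcp_at_ia = tcp_at(ia))
}
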