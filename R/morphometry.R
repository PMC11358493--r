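# Morphometry: nuclei segmentation and density binning, labeled region
# masks, rigid registration with sum preservation, dose-rate-volume
# histograms, and regional S-value dosimetry.

#' Construct a labeled region mask
#'
#' @param labels Integer matrix/array of region labels (0 = background).
#' @param legend Named character vector mapping label (as character) to
#'   region name, e.g. `c("1" = "cortex", "2" = "ISOM/OSOM")`.
#' @return A `region_mask`.
#' @export
region_mask <- function(labels, legend) {
  present <- setdiff(unique(as.integer(labels)), 0L)
  if (!all(as.character(present) %in% names(legend))) {
    abort("every nonzero label must appear in the legend",
          class = "alphadose3d_validation_error")
  }
  structure(list(labels = labels, legend = legend), class = "region_mask")
}

#' Segment cell nuclei by thresholding + distance-transform watershed
#'
#' Otsu threshold (intensity-scale invariant) -> distance transform ->
#' watershed split of touching nuclei -> area filter, then centroids are
#' binned onto the (coarser) autoradiograph voxel grid to give cells per
#' voxel.
#'
#' @param image Grayscale matrix (nuclei bright; values any positive
#'   scale).
#' @param min_area,max_area Accepted component area range in pixels
#'   (0 < min < max).
#' @param bin_factor Image pixels per DAR voxel along each axis (>= 1);
#'   1 keeps the image grid.
#' @param watershed_tolerance Minimum distance-map depth separating two
#'   objects (EBImage watershed tolerance).
#' @return A list with `centroids` (tibble `x`, `y`, `area_px`) and
#'   `density` (matrix of cells per DAR voxel, a nuclei-density map).
#' @export
segment_nuclei <- function(image, min_area, max_area, bin_factor = 1,
                           watershed_tolerance = 0.5) {
  stopifnot(is.matrix(image), min_area > 0, max_area > min_area)
  out_dim <- ceiling(dim(image) / bin_factor)
  empty <- list(centroids = tibble(x = numeric(), y = numeric(),
                                   area_px = numeric()),
                density = matrix(0, out_dim[1], out_dim[2]))
  rng <- range(image)
  if (rng[2] <= rng[1]) return(empty) # blank image
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm))
  binary <- norm > thr
  if (!any(binary)) return(empty)
  dm <- EBImage::distmap(EBImage::Image(binary))
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  lab <- EBImage::imageData(labels)
  n <- max(lab)
  if (n == 0) return(empty)
  areas <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(areas >= min_area & areas <= max_area)
  if (length(keep) == 0) return(empty)
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  cx <- tapply(idx[, 1], lv, mean)[as.character(keep)]
  cy <- tapply(idx[, 2], lv, mean)[as.character(keep)]
  centroids <- tibble(x = as.numeric(cx), y = as.numeric(cy),
                      area_px = areas[keep])
  density <- matrix(0, out_dim[1], out_dim[2])
  bi <- pmin(ceiling(centroids$x / bin_factor), out_dim[1])
  bj <- pmin(ceiling(centroids$y / bin_factor), out_dim[2])
  for (k in seq_along(bi)) density[bi[k], bj[k]] <- density[bi[k], bj[k]] + 1
  list(centroids = centroids, density = density)
}

#' Apply a rigid (rotation + translation) transform to an image
#'
#' Rotates by `theta_deg` about the image center, then translates by
#' `(tx, ty)` pixels, resampling bilinearly with zero fill.
#'
#' @param img Numeric matrix.
#' @param tx,ty Translation in pixels (row, column directions).
#' @param theta_deg Rotation angle in degrees (counter-clockwise in
#'   row/column coordinates).
#' @return Transformed matrix, same shape.
#' @export
apply_rigid <- function(img, tx = 0, ty = 0, theta_deg = 0) {
  nr <- nrow(img); nc <- ncol(img)
  th <- theta_deg * pi / 180
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  # output pixel (i, j) samples the input at the inverse transform
  grid <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  di <- grid$i - cr - tx
  dj <- grid$j - cc - ty
  si <- cos(th) * di + sin(th) * dj + cr
  sj <- -sin(th) * di + cos(th) * dj + cc
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  pix <- function(ii, jj) {
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    v <- numeric(length(ii))
    v[ok] <- img[cbind(ii[ok], jj[ok])]
    v
  }
  v <- (1 - fi) * (1 - fj) * pix(i0, j0) +
    fi * (1 - fj) * pix(i0 + 1, j0) +
    (1 - fi) * fj * pix(i0, j0 + 1) +
    fi * fj * pix(i0 + 1, j0 + 1)
  matrix(v, nr, nc)
}

#' Rigid registration by mean-squared-error minimization
#'
#' Finds the translation + rotation of `moving` that minimizes the MSE
#' against `fixed`, via a coarse angle/centroid-shift initialization
#' followed by Nelder-Mead refinement. The resampled image is rescaled so
#' that its pixel sum equals the moving image's sum (activity
#' conservation under interpolation).
#'
#' @param moving,fixed Numeric matrices of the same shape and pixel size.
#' @param theta_grid_deg Coarse initialization angles.
#' @return A list with `tx`, `ty`, `theta_deg`, `mse`, and `resampled`
#'   (sum-preserved transformed moving image).
#' @export
rigid_register <- function(moving, fixed,
                           theta_grid_deg = seq(-10, 10, by = 2.5)) {
  stopifnot(all(dim(moving) == dim(fixed)))
  centroid <- function(m) {
    tot <- sum(m)
    if (tot == 0) return(c((nrow(m) + 1) / 2, (ncol(m) + 1) / 2))
    c(sum(row(m) * m), sum(col(m) * m)) / tot
  }
  mse <- function(p) mean((apply_rigid(moving, p[1], p[2], p[3]) - fixed)^2)
  cf <- centroid(fixed)
  starts <- lapply(theta_grid_deg, function(th) {
    cm <- centroid(apply_rigid(moving, 0, 0, th))
    c(cf[1] - cm[1], cf[2] - cm[2], th)
  })
  vals <- vapply(starts, mse, numeric(1))
  best <- starts[[which.min(vals)]]
  opt <- optim(best, mse, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  if (!opt$convergence %in% c(0, 1)) {
    abort(sprintf("registration failed to converge (final MSE %.4g)", opt$value),
          class = "alphadose3d_registration_error")
  }
  res <- apply_rigid(moving, opt$par[1], opt$par[2], opt$par[3])
  sm <- sum(moving); sr <- sum(res)
  if (sr > 0) res <- res * (sm / sr)
  list(tx = opt$par[1], ty = opt$par[2], theta_deg = opt$par[3],
       mse = opt$value, resampled = res)
}

#' Erode the positive contour of a density map
#'
#' Voxels in the edge band of the `map > 0` region (those removed by a
#' square-kernel morphological erosion of the positive mask) are set to
#' zero; the interior is unchanged. Used to de-sensitize TCP products to
#' registration error at tissue edges.
#'
#' @param map Numeric or logical matrix.
#' @param erosion_px Structuring-element side in pixels (default 5).
#' @return Matrix of the same shape.
#' @export
erode_positive_contour <- function(map, erosion_px = 5) {
  m <- map * 1 # logical -> numeric
  pos <- m > 0
  if (!any(pos)) return(m)
  brush <- EBImage::makeBrush(erosion_px, shape = "box")
  eroded <- EBImage::imageData(EBImage::erode(EBImage::Image(pos * 1), brush))
  m * (eroded > 0)
}

#' Dose-rate-volume histogram per labeled region
#'
#' Differential and cumulative (fraction of region voxels at or above a
#' dose rate) histograms per region, with region mean dose rates and their
#' ratios to the first region of the legend.
#'
#' @param dose A `dose_rate_volume`/`dose_rate_image` or bare array
#'   (mGy/h).
#' @param mask A [region_mask()] of the same shape.
#' @param bins Number of histogram bins, or a vector of bin edges spanning
#'   the dose range.
#' @return A `drvh` tibble (`region`, `bin_lo`, `bin_hi`, `n_voxels`,
#'   `frac`, `cum_frac_ge_lo`) with attributes `region_stats` (tibble:
#'   `region`, `n_voxels`, `mean`, `ratio_to_first`) and `units`.
#' @export
drvh <- function(dose, mask, bins = 30) {
  if (inherits(dose, "dose_rate_volume") || inherits(dose, "dose_rate_image")) {
    dose <- dose$dose_rate
  }
  stopifnot(inherits(mask, "region_mask"))
  if (!all(dim(dose) == dim(mask$labels))) {
    abort("dose and mask shapes differ", class = "alphadose3d_contract_error")
  }
  labels_present <- names(mask$legend)[
    as.integer(names(mask$legend)) %in% unique(as.integer(mask$labels))]
  empty <- setdiff(names(mask$legend), labels_present)
  if (length(empty) > 0) {
    warn(paste("empty regions excluded:",
               paste(mask$legend[empty], collapse = ", ")))
  }
  vals_all <- dose[mask$labels > 0]
  edges <- if (length(bins) == 1) {
    lo <- min(vals_all); hi <- max(vals_all)
    if (hi <= lo) { # degenerate range (uniform dose)
      lo <- lo - 0.5
      hi <- hi + 0.5
    }
    seq(lo, hi, length.out = bins + 1)
  } else sort(bins)
  hist_tbl <- purrr::map_dfr(labels_present, function(lb) {
    region <- mask$legend[[lb]]
    v <- dose[mask$labels == as.integer(lb)]
    # clamp into the edge span so counts always partition the region
    vc <- pmin(pmax(v, edges[1]), edges[length(edges)])
    cnt <- graphics::hist(vc, breaks = edges, plot = FALSE)$counts
    tibble(
      region = region,
      bin_lo = head(edges, -1), bin_hi = tail(edges, -1),
      n_voxels = cnt,
      frac = cnt / length(v),
      cum_frac_ge_lo = rev(cumsum(rev(cnt))) / length(v)
    )
  })
  stats_tbl <- purrr::map_dfr(labels_present, function(lb) {
    v <- dose[mask$labels == as.integer(lb)]
    tibble(region = mask$legend[[lb]], n_voxels = length(v), mean = mean(v))
  })
  stats_tbl$ratio_to_first <- stats_tbl$mean / stats_tbl$mean[1]
  structure(hist_tbl, region_stats = stats_tbl, units = "mGy/h",
            class = c("drvh", class(hist_tbl)))
}

#' Region statistics of a DRVH
#'
#' @param x A `drvh`.
#' @return The `region_stats` tibble (region, n_voxels, mean,
#'   ratio_to_first).
#' @export
drvh_stats <- function(x) attr(x, "region_stats")

#' Regional S-value dose rates
#'
#' Distributes a total measured activity over compartments by relative
#' activity fractions and applies an S-value matrix:
#' `rate(target) = sum_source A f_source S(source -> target)`.
#'
#' @param total_activity_Bq Total organ activity (Bq).
#' @param fractions Named numeric vector of per-region activity fractions
#'   (must sum to 1 within 1e-6).
#' @param s_matrix Square numeric matrix (source rows x target columns) of
#'   S values in Gy/(Bq s), dimnames matching `names(fractions)`.
#' @return A tibble with `region`, `dose_rate_mGy_h`.
#' @export
regional_s_dose <- function(total_activity_Bq, fractions, s_matrix) {
  if (abs(sum(fractions) - 1) > 1e-6) {
    abort("activity fractions must sum to 1", class = "alphadose3d_contract_error")
  }
  stopifnot(is.matrix(s_matrix), nrow(s_matrix) == ncol(s_matrix),
            nrow(s_matrix) == length(fractions))
  if (!is.null(rownames(s_matrix))) {
    s_matrix <- s_matrix[names(fractions), names(fractions)]
  }
  rate_Gy_s <- as.numeric(total_activity_Bq * (fractions %*% s_matrix))
  tibble(region = names(fractions), dose_rate_mGy_h = rate_Gy_s * 1000 * 3600)
}

#' Combine regions of an S-value matrix by unweighted averaging
#'
#' When two anatomical segments are analyzed as one (e.g. inner + outer
#' stripes of the outer medulla), their S values are averaged
#' (mass-unweighted), both as sources and as targets.
#'
#' @param s_matrix Square named S-value matrix.
#' @param regions Character vector of >= 2 region names to combine.
#' @param new_name Name of the combined region.
#' @return The reduced S-value matrix.
#' @export
combine_s_regions <- function(s_matrix, regions, new_name) {
  stopifnot(all(regions %in% rownames(s_matrix)))
  keep <- setdiff(rownames(s_matrix), regions)
  comb_row <- colMeans(s_matrix[regions, , drop = FALSE])
  m2 <- rbind(s_matrix[keep, , drop = FALSE], comb_row)
  rownames(m2) <- c(keep, new_name)
  comb_col <- rowMeans(m2[, regions, drop = FALSE])
  m3 <- cbind(m2[, keep, drop = FALSE], comb_col)
  colnames(m3) <- c(keep, new_name)
  m3[c(keep, new_name), c(keep, new_name)]
}

#' Read an S-value matrix from CSV (`source`, `target`, `s_value`)
#'
#' @param path CSV path (values in Gy/(Bq s)).
#' @return A square named matrix.
#' @export
read_s_matrix <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("source", "target", "s_value") %in% names(df)))
  regions <- unique(c(df$source, df$target))
  m <- matrix(0, length(regions), length(regions),
              dimnames = list(regions, regions))
  m[cbind(df$source, df$target)] <- df$s_value
  m
}
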