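# ggplot2 methods for the result types.

#' @export
autoplot.drvh <- function(object, ..., cumulative = TRUE) {
  if (cumulative) {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$bin_lo, y = .data$cum_frac_ge_lo,
                                 colour = .data$region)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = paste0("Dose rate (", attr(object, "units"), ")"),
                    y = "Fraction of region volume ≥ dose rate",
                    colour = "Region") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                 y = .data$frac, fill = .data$region)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = paste0("Dose rate (", attr(object, "units"), ")"),
                    y = "Fraction of region volume", fill = "Region") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.biexp_fit <- function(object, ...) {
  tmax <- max(object$data$time_h)
  grid <- tibble(time_h = seq(0, tmax * 1.1, length.out = 200))
  grid$central <- trc_rate(object, grid$time_h)
  grid$upper <- trc_rate(object, grid$time_h, "upper")
  grid$lower <- trc_rate(object, grid$time_h, "lower")
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_h, y = .data$dose_rate_mGy_h)) +
    ggplot2::geom_ribbon(data = grid,
                         ggplot2::aes(x = .data$time_h, ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$time_h, y = .data$central),
                       inherit.aes = FALSE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time post-injection (h)", y = "Dose rate (mGy/h)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tcp_result <- function(object, ...) {
  ggplot2::ggplot(object$slice_tcp,
                  ggplot2::aes(x = .data$slice, y = .data$tcp)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Slice (cut order)", y = "Slice TCP") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.deescalation_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("mean_slice_tcp", "volume_tcp"),
                              names_to = "metric", values_to = "tcp")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ia_kBq, y = .data$tcp,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Injected activity (kBq)", y = "TCP",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gamma_result <- function(object, ...) {
  df <- tibble(gamma = as.numeric(object$gamma_map))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = expression(gamma), y = "Voxels") +
    ggplot2::theme_minimal()
}

#' Raster plot of a dose-rate image
#'
#' @param img A `dose_rate_image` (or matrix).
#' @param pixel_size_um Pixel size when a matrix is given.
#' @return A ggplot.
#' @export
plot_dose_rate <- function(img, pixel_size_um = NULL) {
  if (inherits(img, "dose_rate_image")) {
    pixel_size_um <- img$pixel_size_um
    img <- img$dose_rate
  }
  px <- pixel_size_um %||% 1
  df <- expand.grid(x = seq_len(nrow(img)), y = seq_len(ncol(img)))
  df$dose_rate <- as.numeric(img)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * px, y = .data$y * px,
                                   fill = .data$dose_rate)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = "Gy/h") +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
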