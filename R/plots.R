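#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot intensity traces by channel
#'
#' @param traces A tibble with `time_s`, `intensity`, `channel`.
#' @return A ggplot.
#' @export
plot_traces <- function(traces) {
  ggplot2::ggplot(traces,
                  ggplot2::aes(x = .data$time_s, y = .data$intensity,
                               colour = factor(.data$channel))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "intensity (a.u.)",
                  colour = "channel") +
    ggplot2::theme_minimal()
}

#' @method autoplot phase_shift
#' @export
autoplot.phase_shift <- function(object, ...) {
  ggplot2::ggplot(object$correlation_curve,
                  ggplot2::aes(x = .data$lag_s, y = .data$correlation)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lag, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "lag (s)", y = "normalized cross-correlation",
                  title = sprintf("phase shift %.2f s", object$lag)) +
    ggplot2::theme_minimal()
}

#' @method autoplot aligned_profile
#' @export
autoplot.aligned_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profile,
                              cols = c("reference_mean", "follower_mean"),
                              names_to = "channel", values_to = "mean")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rel_time_s, y = .data$mean,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$follower_shift, linetype = 2) +
    ggplot2::labs(x = "time from reference peak (s)",
                  y = "mean detrended intensity") +
    ggplot2::theme_minimal()
}

#' @method autoplot averaged_bar_image
#' @export
autoplot.averaged_bar_image <- function(object, ...) {
  px <- attr(object, "pixel_size")
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$value <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$col - 1) * px / 1000,
                                   y = (.data$row - 1) * px / 1000,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "μm", y = "μm", fill = "a.u.",
                  title = sprintf("average of %d bars (%g nm)",
                                  attr(object, "n_bars"),
                                  attr(object, "width_nm"))) +
    ggplot2::theme_minimal()
}

#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$width_nm,
                                       y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$density - .data$sem,
      ymax = .data$density + .data$sem)) +
    ggplot2::labs(x = "nanobar width (nm)",
                  y = "nanobar-end density (protein / lipid)") +
    ggplot2::theme_minimal()
}

#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, n_grid = 200, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration_uM,
                                       y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "concentration (μM)",
                  y = "nanobar-end density") +
    ggplot2::theme_minimal()
  if (!is.null(d[["sem"]])) {
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$density - .data$sem,
      ymax = .data$density + .data$sem), width = 0)
  }
  if (object$converged) {
    e <- setNames(object$estimate$estimate, object$estimate$term)
    grid <- tibble::tibble(
      concentration_uM = seq(min(d$concentration_uM),
                             max(d$concentration_uM),
                             length.out = n_grid))
    grid$density <- hill_model(grid$concentration_uM, e["Bmax"],
                               e["K_D"], e["H"])
    p <- p + ggplot2::geom_line(data = grid, colour = "red")
  }
  p
}

#' @method autoplot frap_fit
#' @export
autoplot.frap_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s,
                                       y = .data$intensity)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "normalized intensity") +
    ggplot2::theme_minimal()
  if (!object$no_recovery && !is.null(object$fitted_model)) {
    bi <- attr(d, "bleach_index")
    post <- d[bi:nrow(d), ]
    t <- post$time_s - post$time_s[1]
    pred <- object$I0 + (object$plateau - object$I0) *
      (1 - 2^(-t / object$t_half))
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(time_s = post$time_s, intensity = pred),
      colour = "red")
  }
  p
}
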