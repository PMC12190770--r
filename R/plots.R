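#' Plot a fitted three-parameter logistic
#'
#' Response points with the fitted curve; the dashed guides mark the
#' inflection point (the 50% crossing) and the upper asymptote.
#'
#' @param object A `logistic3_fit`.
#' @param n_curve Curve resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.logistic3_fit <- function(object, n_curve = 200, ...) {
  dat <- object$data
  xx <- seq(min(dat$x), max(dat$x), length.out = n_curve)
  curve <- tibble::tibble(x = xx,
                          y = predict(object, tibble::tibble(x = xx)))
  xlab <- if (object$direction == "dose") "Irradiance (W/m²)" else "Time (min)"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_line(data = curve, color = "#2166ac", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = object$c, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_vline(xintercept = object$b, linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = xlab, y = "Dark-subtracted normalized signal (AU)",
                  subtitle = sprintf("a = %.3g, b = %.3g, c = %.3g, R² = %.3f",
                                     object$a, object$b, object$c,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a kinetics report
#'
#' Dark-subtracted observations with the on- and off-phase logistic fits
#' (off phase drawn in absolute time).
#'
#' @param object A `kinetics_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinetics_report <- function(object, ...) {
  obs <- object$observations
  pl <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$axis_value, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$bio_replicate), alpha = 0.8) +
    ggplot2::labs(x = "Time (min)",
                  y = "Dark-subtracted normalized signal (AU)",
                  shape = "Replicate") +
    ggplot2::theme_minimal()
  t_end <- object$config$exposure_end_min
  if (!is.null(object$fit_on) && !object$fit_on$degenerate) {
    xx <- seq(min(obs$axis_value), t_end, length.out = 150)
    cv <- tibble::tibble(x = xx, y = predict(object$fit_on, tibble::tibble(x = xx)))
    pl <- pl + ggplot2::geom_line(data = cv, ggplot2::aes(x = .data$x, y = .data$y),
                                  color = "#2166ac", linewidth = 0.8)
  }
  if (!is.null(object$fit_off) && !object$fit_off$degenerate) {
    xx <- seq(0, max(obs$axis_value) - t_end, length.out = 150)
    cv <- tibble::tibble(x = xx + t_end,
                         y = predict(object$fit_off, tibble::tibble(x = xx)))
    pl <- pl + ggplot2::geom_line(data = cv, ggplot2::aes(x = .data$x, y = .data$y),
                                  color = "#b2182b", linewidth = 0.8)
  }
  pl + ggplot2::geom_vline(xintercept = t_end, linetype = "dotted")
}

#' Plot a dose report
#' @param object A `dose_report`.
#' @param ... Unused.
#' @return A ggplot (log10 x scale, zero plotted at the smallest non-zero step).
#' @export
autoplot.dose_report <- function(object, ...) {
  autoplot(object$fit) +
    ggplot2::scale_x_continuous(trans = "pseudo_log")
}

#' Plot a maximum-intensity projection
#'
#' @param volume A [channel_volume()].
#' @param channel Channel name.
#' @param mask Optional [region_mask()] applied before projection (the
#'   "nuclear" projection uses the DAPI mask).
#' @return A ggplot raster of the (y, x) projection.
#' @export
plot_projection <- function(volume, channel, mask = NULL) {
  proj <- max_projection(volume, channel, mask)
  df <- tidyr::expand_grid(y = seq_len(nrow(proj)), x = seq_len(ncol(proj)))
  df$intensity <- as.vector(t(proj))[(df$y - 1L) * ncol(proj) + df$x]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "AU") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s max projection", channel)) +
    ggplot2::theme_void()
}
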