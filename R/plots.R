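#' Plot a conduction-rate scan
#'
#' Per-length mean K+ currents with standard-deviation error bars, plus the
#' Gaussian fit curve when a `current_fit` is supplied.
#'
#' @param object A `length_scan`.
#' @param fit Optional `current_fit` from [fit_gaussian_current()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.length_scan <- function(object, fit = NULL, ...) {
  s <- object$summary
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$percent,
                                       y = .data$mean_current)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_current - .data$sd_current,
                   ymax = .data$mean_current + .data$sd_current),
      width = 0.4, na.rm = TRUE) +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(x = "filter length change (%)",
                  y = expression(K^"+" ~ "current (ions/" * mu * "s)"))
  if (!is.null(fit)) {
    e <- fit$estimate
    xs <- seq(min(s$percent), max(s$percent), length.out = 200)
    curve <- tibble(percent = xs,
                    mean_current = e["I0"] *
                      exp(-(xs - e["x0"])^2 / (2 * e["w"]^2)))
    p <- p + ggplot2::geom_line(data = curve, colour = "black")
  }
  p
}

#' Plot a test-charge potential profile
#'
#' @param object A `potential_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.potential_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$z_pm, y = .data$energy_ev)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$z_max_pm, linetype = 3) +
    ggplot2::labs(
      x = "axial position z (pm)", y = expression(E[p] ~ "(eV)"),
      subtitle = sprintf("%s to %s, barrier %.2f eV at t = %.1f ps",
                         object$from, object$to, object$barrier_ev,
                         object$time_fs / 1000))
}

#' Plot oxygen fluctuation histograms
#'
#' Relative-frequency histograms of the z-deviation and the total (3D)
#' deviation of the recorded ring oxygens from their mean positions.
#'
#' @param object A `fluctuation_stats`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fluctuation_stats <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$mid_pm, y = .data$frequency)) +
    ggplot2::geom_col(width = NA, fill = "grey35") +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = "deviation from mean position (pm)",
                  y = "relative frequency")
}

#' Plot the energy trace of a run
#'
#' Kinetic, potential and total energy against time; useful to watch
#' thermalization and to verify conservation in closed runs.
#'
#' @param object A `filter_sim` run with `energy_every_fs` set.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filter_sim <- function(object, ...) {
  if (is.null(object$energy))
    abort("run with `energy_every_fs` to record an energy trace.")
  long <- tidyr::pivot_longer(
    object$energy,
    c("ke_carbonyl_ev", "ke_translation_ev", "pe_ev", "total_ev"),
    names_to = "component", values_to = "energy_ev")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_fs / 1000,
                                     y = .data$energy_ev,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "energy (eV)")
}
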