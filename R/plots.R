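#' Plot a titration fit
#'
#' Ellipticity-at-288 nm data with the fitted sigmoid and a marker at
#' the transitional pH.
#'
#' @param object A [fit_titration()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot titration_fit
#' @export
autoplot.titration_fit <- function(object, ...) {
  grid <- tibble(ph = seq(min(object$data$ph), max(object$data$ph),
                          length.out = 200))
  grid$ellipticity_mdeg <- object$theta_unfolded +
    (object$theta_folded - object$theta_unfolded) /
    (1 + 10^(object$hill * (grid$ph - object$ph_t)))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$ph, y = .data$ellipticity_mdeg)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$ph_t, linetype = "dashed") +
    ggplot2::labs(
      x = "pH", y = "ellipticity at 288 nm (mdeg)",
      title = sprintf("pH_T = %.2f ± %.2f", object$ph_t, object$ph_t_se)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a thermal difference spectrum
#'
#' @param object A [compute_tds()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tds_spectrum
#' @export
autoplot.tds_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength_nm,
                                       y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "normalized ΔA",
                  title = "thermal difference spectrum") +
    ggplot2::theme_minimal()
}

#' Plot a dU conversion-count distribution
#'
#' @param object A [assign_du_counts()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot species_table
#' @export
autoplot.species_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$k, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "dU conversions per molecule (k)",
                  y = "abundance-weighted frequency") +
    ggplot2::theme_minimal()
}

#' Plot melting/annealing ramps with their first-derivative midpoints
#'
#' @param curves A curve tibble (see [melt_stats()]).
#' @param window Smoothing window for the midpoint estimates.
#' @return A ggplot object with one vertical line per
#'   direction-averaged midpoint.
#' @export
plot_melt_curves <- function(curves, window = 5) {
  stats <- melt_stats(curves, window = window)
  mid <- tibble(direction = c("melt", "anneal"),
                midpoint = c(stats$tm_mean, stats$ta_mean))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$temperature_C,
                                       y = .data$signal,
                                       colour = .data$direction,
                                       group = interaction(.data$direction,
                                                           .data$replicate))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_vline(data = mid,
                        ggplot2::aes(xintercept = .data$midpoint,
                                     colour = .data$direction),
                        linetype = "dashed") +
    ggplot2::labs(x = "temperature (°C)", y = "A295",
                  title = sprintf("Tm %.1f / Ta %.1f / hysteresis %.1f °C",
                                  stats$tm_mean, stats$ta_mean,
                                  stats$hysteresis)) +
    ggplot2::theme_minimal()
}

#' Plot a length profile: stability versus deletion frequency
#'
#' @param profile A profile tibble (see [tccc_length_profile()]).
#' @param ph_threshold Transitional-pH threshold drawn as a reference
#'   line.
#' @return A ggplot object.
#' @export
plot_length_profile <- function(profile = tccc_length_profile(),
                                ph_threshold = 7.0) {
  d <- filter(profile, is.finite(.data$ph_t),
              is.finite(.data$deletion_fraction))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ph_t,
                                  y = .data$deletion_fraction)) +
    ggplot2::geom_vline(xintercept = ph_threshold, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene),
                       vjust = -1, size = 3) +
    ggplot2::scale_y_continuous(limits = c(-0.05, 1.1)) +
    ggplot2::labs(x = "transitional pH (in vitro)",
                  y = "deletion fraction (clones)",
                  size = "repeat copies n") +
    ggplot2::theme_minimal()
}
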