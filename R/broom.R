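#' Tidy a titration fit
#'
#' @param x A [fit_titration()] result.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy titration_fit
#' @export
tidy.titration_fit <- function(x, ...) {
  tibble(
    term = c("ph_t", "hill", "theta_folded", "theta_unfolded"),
    estimate = c(x$ph_t, x$hill, x$theta_folded, x$theta_unfolded),
    std.error = c(x$ph_t_se, x$hill_se, NA_real_, NA_real_)
  )
}

#' One-row summaries of imotifkit result objects
#'
#' `glance()` methods returning one-row tibbles: for a `titration_fit`,
#' the transitional pH and fit diagnostics; for `deletion_calls`, the
#' event count and deletion frequency; for a `species_table`, the
#' conversion-count distribution summary.
#'
#' @param x A fitted/derived imotifkit object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance-imotifkit
NULL

#' @rdname glance-imotifkit
#' @method glance titration_fit
#' @export
glance.titration_fit <- function(x, ...) {
  tibble(
    ph_t = x$ph_t, ph_t_se = x$ph_t_se, hill = x$hill,
    theta_folded = x$theta_folded, theta_unfolded = x$theta_unfolded,
    rss = x$rss, n = x$n, extrapolated = x$extrapolated
  )
}

#' Augment titration data with fitted values
#'
#' @param x A [fit_titration()] result.
#' @param ... Unused.
#' @return The fitting data with `.fitted` and `.resid` columns.
#' @method augment titration_fit
#' @export
augment.titration_fit <- function(x, ...) {
  fitted <- x$theta_unfolded + (x$theta_folded - x$theta_unfolded) /
    (1 + 10^(x$hill * (x$data$ph - x$ph_t)))
  mutate(x$data, .fitted = fitted, .resid = .data$ellipticity_mdeg - fitted)
}
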