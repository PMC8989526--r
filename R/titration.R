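#' Fit a CD pH titration for the transitional pH
#'
#' Fits ellipticity at 288 nm versus pH to a four-parameter Hill-type
#' sigmoid,
#' \deqn{\theta(pH) = \theta_u + (\theta_f - \theta_u) /
#'   (1 + 10^{n_H (pH - pH_T)})}
#' by nonlinear least squares (Levenberg-Marquardt). The transitional pH
#' (pH_T) is the inflection point, i.e. the pH at which half the
#' population is folded; its standard error comes from the estimated
#' parameter covariance. Starting values are data-driven: baselines from
#' the 10% extreme-pH quantile means, pH_T from linear interpolation of
#' the half-amplitude crossing, Hill slope 1. The slope is bounded to
#' (0.2, 10] to exclude degenerate step fits.
#'
#' @param series A data frame with columns `ph` (or `pH`) and
#'   `ellipticity_mdeg`; an optional `replicate` column is pooled into
#'   one fit. Needs >= 6 distinct pH values spanning >= 1.5 units, and a
#'   signal range exceeding 3x the noise estimate.
#' @return An object of class `titration_fit` with elements `ph_t`,
#'   `ph_t_se`, `hill`, `hill_se`, `theta_folded`, `theta_unfolded`,
#'   `rss`, `n`, `extrapolated`, `data` and the underlying `nls` model.
#'   Use [tidy()], [glance()], [augment()] or [autoplot()] on it.
#' @examples
#' ser <- sim_titration(ph_t = 7.1, cfg = sim_config(1, 0.02, 3))
#' fit <- fit_titration(ser)
#' glance(fit)
#' @export
fit_titration <- function(series) {
  stopifnot(is.data.frame(series))
  if (!"ph" %in% names(series) && "pH" %in% names(series)) {
    series$ph <- series$pH
  }
  if (!all(c("ph", "ellipticity_mdeg") %in% names(series))) {
    abort("`series` must have columns `ph` and `ellipticity_mdeg`")
  }
  ph <- series$ph
  theta <- series$ellipticity_mdeg
  if (length(unique(ph)) < 6) abort("need >= 6 distinct pH points")
  if (diff(range(ph)) < 1.5) abort("pH span must be >= 1.5 units")
  # noise estimate: replicate scatter if available, else local differences
  noise <- if ("replicate" %in% names(series) &&
               length(unique(series$replicate)) > 1) {
    pooled <- series |>
      group_by(.data$ph) |>
      summarise(s = sd(.data$ellipticity_mdeg), .groups = "drop")
    mean(pooled$s, na.rm = TRUE)
  } else {
    ord <- order(ph)
    mad(diff(theta[ord])) / sqrt(2)
  }
  if (!is.finite(noise)) noise <- 0
  if (diff(range(theta)) <= 3 * noise) {
    abort("signal range does not exceed 3x the noise estimate; no transition to fit")
  }
  lo_q <- stats::quantile(ph, 0.10)
  hi_q <- stats::quantile(ph, 0.90)
  theta_f0 <- mean(theta[ph <= lo_q])   # folded baseline at low pH
  theta_u0 <- mean(theta[ph >= hi_q])
  half <- (theta_f0 + theta_u0) / 2
  agg <- arrange(summarise(group_by(tibble(ph = ph, theta = theta), .data$ph),
                           theta = mean(.data$theta), .groups = "drop"), .data$ph)
  cross <- which(diff(sign(agg$theta - half)) != 0)
  ph_t0 <- if (length(cross) > 0) {
    i <- cross[1]
    approx(agg$theta[c(i, i + 1)], agg$ph[c(i, i + 1)], xout = half,
           ties = "ordered")$y
  } else {
    median(ph)
  }
  if (!is.finite(ph_t0)) ph_t0 <- median(ph)
  dat <- tibble(ph = ph, ellipticity_mdeg = theta)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ellipticity_mdeg ~ theta_u + (theta_f - theta_u) /
        (1 + 10^(hill * (ph - ph_t))),
      data = dat,
      start = list(theta_f = theta_f0, theta_u = theta_u0, hill = 1,
                   ph_t = ph_t0),
      lower = c(theta_f = -Inf, theta_u = -Inf, hill = 0.2,
                ph_t = min(ph) - 3),
      upper = c(theta_f = Inf, theta_u = Inf, hill = 10,
                ph_t = max(ph) + 3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort(paste0("titration fit did not converge: ",
                                     conditionMessage(e)))
  )
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  extrapolated <- cf[["ph_t"]] < min(ph) || cf[["ph_t"]] > max(ph)
  if (extrapolated) {
    warn("fitted pH_T lies outside the sampled pH span (extrapolation)")
  }
  structure(
    list(
      ph_t = unname(cf["ph_t"]), ph_t_se = unname(se[names(cf) == "ph_t"]),
      hill = unname(cf["hill"]), hill_se = unname(se[names(cf) == "hill"]),
      theta_folded = unname(cf["theta_f"]),
      theta_unfolded = unname(cf["theta_u"]),
      rss = sum(stats::residuals(fit)^2),
      n = nrow(dat),
      extrapolated = extrapolated,
      data = dat,
      model = fit
    ),
    class = "titration_fit"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("<titration_fit>\n")
  cat(sprintf("  pH_T        %.3f +/- %.3f\n", x$ph_t, x$ph_t_se))
  cat(sprintf("  Hill slope  %.3f\n", x$hill))
  cat(sprintf("  baselines   folded %.2f / unfolded %.2f mdeg\n",
              x$theta_folded, x$theta_unfolded))
  cat(sprintf("  rss %.4g over %d points%s\n", x$rss, x$n,
              if (x$extrapolated) "  [extrapolated pH_T]" else ""))
  invisible(x)
}

#' Predicted i-motif (folded) fraction at a given pH
#'
#' Evaluates the folded fraction implied by a titration fit,
#' `f(pH) = 1 / (1 + 10^(n_H (pH - pH_T)))`. At `pH = pH_T` the fraction
#' is exactly 0.5; for positive Hill slopes it decreases with pH.
#'
#' @param fit A [fit_titration()] result, or any list with elements
#'   `ph_t` and `hill`.
#' @param ph pH value(s) at which to evaluate.
#' @return Numeric vector of folded fractions in `[0, 1]`.
#' @examples
#' fraction_folded(list(ph_t = 7.1, hill = 2), ph = 5.3)
#' @export
fraction_folded <- function(fit, ph) {
  stopifnot(is.list(fit), !is.null(fit$ph_t), !is.null(fit$hill))
  1 / (1 + 10^(fit$hill * (ph - fit$ph_t)))
}

#' Classify a CD spectrum by its band signature
#'
#' Rule-based classification of a 200-320 nm CD scan after light
#' smoothing: an i-motif shows a positive band with its maximum at
#' 285-292 nm and a negative band at 255-270 nm; a parallel
#' G-quadruplex shows a positive band at 260-268 nm and a negative band
#' at 235-245 nm; anything else (including flat, low-amplitude scans) is
#' `unfolded_or_other`.
#'
#' @param spectrum A data frame with columns `wavelength_nm` and
#'   `ellipticity_mdeg`; the grid must cover 230-310 nm.
#' @param min_amplitude Minimum peak-to-trough ellipticity (mdeg) for a
#'   spectrum to count as structured.
#' @return One of `"i_motif"`, `"parallel_g4"`, `"unfolded_or_other"`.
#' @export
classify_cd_spectrum <- function(spectrum, min_amplitude = 1) {
  stopifnot(is.data.frame(spectrum),
            all(c("wavelength_nm", "ellipticity_mdeg") %in% names(spectrum)))
  wl <- spectrum$wavelength_nm
  if (min(wl) > 230 || max(wl) < 310) {
    abort("insufficient wavelength coverage: need 230-310 nm")
  }
  d <- spectrum[order(wl), ]
  d <- d[d$wavelength_nm >= 230 & d$wavelength_nm <= 310, ]
  y <- if (nrow(d) >= 9) stats::runmed(d$ellipticity_mdeg, 5) else d$ellipticity_mdeg
  if (diff(range(y)) < min_amplitude) return("unfolded_or_other")
  wmax <- d$wavelength_nm[which.max(y)]
  wmin <- d$wavelength_nm[which.min(y)]
  if (max(y) > 0 && wmax >= 285 && wmax <= 292 &&
      min(y) < 0 && wmin >= 255 && wmin <= 270) {
    "i_motif"
  } else if (max(y) > 0 && wmax >= 260 && wmax <= 268 &&
             min(y) < 0 && wmin >= 235 && wmin <= 245) {
    "parallel_g4"
  } else {
    "unfolded_or_other"
  }
}
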