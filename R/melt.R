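#' First-derivative midpoint of a melting or annealing curve
#'
#' Implements the first-derivative method: the melting (or annealing)
#' temperature is the temperature at which |dA/dT| is maximal. The
#' signal is first smoothed by a moving-window local quadratic
#' least-squares fit (valid on uneven grids), the derivative is taken by
#' central differences on the smoothed values, and the extremum is
#' refined below grid resolution by parabolic interpolation through the
#' extremum and its two neighbours. Duplicate-temperature points (hold
#' segments at the ends of a ramp) are dropped before analysis.
#'
#' A curve with no resolvable transition (smoothed amplitude below the
#' noise floor) yields `NA` with a `"no transition"` warning rather than
#' an arbitrary temperature.
#'
#' @param curve A data frame with columns `temperature_C` and `signal`
#'   holding one ramp (one direction, one replicate).
#' @param window Odd number of points in the smoothing window (>= 3).
#' @return The midpoint temperature in degC, or `NA_real_` if no
#'   transition is detected.
#' @examples
#' curve <- sim_melt_curve(tm = 40, grid = seq(4, 95, 1))
#' first_derivative_midpoint(curve)
#' @export
first_derivative_midpoint <- function(curve, window = 5) {
  stopifnot(is.data.frame(curve),
            all(c("temperature_C", "signal") %in% names(curve)))
  if ("direction" %in% names(curve) && length(unique(curve$direction)) > 1) {
    abort("`curve` mixes melt and anneal points; analyse one ramp at a time")
  }
  if ("replicate" %in% names(curve) && length(unique(curve$replicate)) > 1) {
    abort("`curve` mixes replicates; analyse one ramp at a time")
  }
  d <- curve[order(curve$temperature_C), c("temperature_C", "signal")]
  d <- d[!duplicated(d$temperature_C), , drop = FALSE]  # trim hold segments
  tt <- d$temperature_C
  y <- d$signal
  n <- length(tt)
  if (n < 10) abort("need at least 10 distinct-temperature points")
  if (any(!is.finite(y))) abort("`signal` contains non-finite values")
  if (window < 3 || window %% 2 == 0) abort("`window` must be odd and >= 3")
  if (window > n) abort("`window` exceeds the number of points")
  half <- (window - 1L) / 2L
  smooth <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    x <- tt[idx] - tt[i]
    fit <- .lm.fit(cbind(1, x, x^2), y[idx])
    fit$coefficients[1]
  }, numeric(1))
  resid_sd <- sd(y - smooth)
  if (diff(range(smooth)) <= max(6 * resid_sd, .Machine$double.eps * 100)) {
    warn("no transition detected (flat curve)")
    return(NA_real_)
  }
  # central differences on the (possibly uneven) grid
  deriv <- numeric(n)
  deriv[1] <- (smooth[2] - smooth[1]) / (tt[2] - tt[1])
  deriv[n] <- (smooth[n] - smooth[n - 1]) / (tt[n] - tt[n - 1])
  mid <- 2:(n - 1)
  deriv[mid] <- (smooth[mid + 1] - smooth[mid - 1]) / (tt[mid + 1] - tt[mid - 1])
  a <- abs(deriv)
  i0 <- which.max(a[mid]) + 1L  # interior extremum
  if (i0 <= 1L || i0 >= n) {
    warn("derivative extremum at grid edge; returning grid temperature")
    return(tt[i0])
  }
  # parabolic refinement through (t, |dA/dT|) at i0-1, i0, i0+1
  x <- tt[(i0 - 1):(i0 + 1)]
  v <- a[(i0 - 1):(i0 + 1)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  A <- (x[3] * (v[2] - v[1]) + x[2] * (v[1] - v[3]) + x[1] * (v[3] - v[2])) / denom
  B <- (x[3]^2 * (v[1] - v[2]) + x[2]^2 * (v[3] - v[1]) + x[1]^2 * (v[2] - v[3])) / denom
  if (A >= 0) return(tt[i0])  # degenerate parabola; fall back to grid point
  vertex <- -B / (2 * A)
  if (vertex < x[1] || vertex > x[3]) tt[i0] else vertex
}

#' Melting statistics over replicate ramps
#'
#' Computes per-replicate first-derivative midpoints for heating (Tm)
#' and cooling (Ta) ramps, their means and sample standard deviations,
#' and the hysteresis. By default hysteresis is the difference of the
#' direction means (`tm_mean - ta_mean`); `"per_replicate"` instead
#' averages paired per-replicate differences (the two agree when
#' replicates are balanced).
#'
#' @param curves A data frame with columns `temperature_C`, `signal`,
#'   `direction` (`"melt"`/`"anneal"`) and `replicate`; a `label` or
#'   `buffer` column, if present, must be constant.
#' @param window Smoothing window passed to
#'   [first_derivative_midpoint()].
#' @param hysteresis_mode `"group_means"` (default) or
#'   `"per_replicate"`.
#' @return A one-row tibble: `tm_mean`, `tm_sd`, `ta_mean`, `ta_sd`,
#'   `hysteresis`, `n_melt`, `n_anneal`.
#' @examples
#' cfg <- sim_config(seed = 1, noise_sd = 0.01, n_replicates = 3)
#' curves <- dplyr::bind_rows(
#'   sim_melt_curve(tm = 40.7, direction = "melt", cfg = cfg),
#'   sim_melt_curve(tm = 30.3, direction = "anneal", cfg = cfg)
#' )
#' melt_stats(curves)
#' @export
melt_stats <- function(curves, window = 5,
                       hysteresis_mode = c("group_means", "per_replicate")) {
  hysteresis_mode <- match.arg(hysteresis_mode)
  stopifnot(is.data.frame(curves))
  need <- c("temperature_C", "signal", "direction", "replicate")
  if (!all(need %in% names(curves))) {
    abort(paste0("`curves` must have columns ", paste(need, collapse = ", ")))
  }
  for (col in intersect(c("label", "buffer"), names(curves))) {
    if (length(unique(curves[[col]])) > 1) {
      abort(paste0("mixed `", col, "` values in one replicate group"))
    }
  }
  mids <- curves |>
    group_by(.data$direction, .data$replicate) |>
    dplyr::group_modify(~ tibble(midpoint = first_derivative_midpoint(.x, window))) |>
    ungroup()
  if (!all(c("melt", "anneal") %in% mids$direction)) {
    abort("need at least one melt and one anneal replicate")
  }
  tm <- mids$midpoint[mids$direction == "melt"]
  ta <- mids$midpoint[mids$direction == "anneal"]
  hyst <- if (hysteresis_mode == "group_means") {
    mean(tm) - mean(ta)
  } else {
    if (length(tm) != length(ta)) {
      abort("per_replicate hysteresis needs balanced melt/anneal replicates")
    }
    mean(tm - ta)
  }
  tibble(
    tm_mean = mean(tm), tm_sd = if (length(tm) > 1) sd(tm) else 0,
    ta_mean = mean(ta), ta_sd = if (length(ta) > 1) sd(ta) else 0,
    hysteresis = hyst,
    n_melt = length(tm), n_anneal = length(ta)
  )
}

#' Thermal difference spectrum
#'
#' Subtracts the folded-state absorbance spectrum (recorded cold, e.g.
#' 4 degC) from the unfolded-state spectrum (recorded hot, e.g. 95 degC)
#' over 220-320 nm and normalizes so the maximum change equals exactly
#' +1. Spectra on different wavelength grids are linearly interpolated
#' onto the folded spectrum's grid, whose overlap must cover 220-320 nm.
#'
#' @param spec_folded,spec_unfolded Data frames with columns
#'   `wavelength_nm` and `absorbance`.
#' @return A tibble of class `tds_spectrum` with columns
#'   `wavelength_nm`, `delta` (normalized so `max(delta) == 1`).
#' @export
compute_tds <- function(spec_folded, spec_unfolded) {
  for (s in list(spec_folded, spec_unfolded)) {
    stopifnot(is.data.frame(s),
              all(c("wavelength_nm", "absorbance") %in% names(s)))
  }
  lo <- max(min(spec_folded$wavelength_nm), min(spec_unfolded$wavelength_nm))
  hi <- min(max(spec_folded$wavelength_nm), max(spec_unfolded$wavelength_nm))
  if (lo > 220 || hi < 320) {
    abort("wavelength overlap must cover 220-320 nm")
  }
  wl <- sort(unique(spec_folded$wavelength_nm))
  wl <- wl[wl >= 220 & wl <= 320]
  a4 <- approx(spec_folded$wavelength_nm, spec_folded$absorbance, wl)$y
  a95 <- approx(spec_unfolded$wavelength_nm, spec_unfolded$absorbance, wl)$y
  delta <- a95 - a4
  m <- max(delta)
  if (!is.finite(m) || m <= 0) {
    abort("degenerate TDS: maximum absorbance change is not positive")
  }
  out <- tibble(wavelength_nm = wl, delta = delta / m)
  class(out) <- c("tds_spectrum", class(out))
  out
}
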