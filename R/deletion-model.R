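#' Probability that an unsuppressed i-motif impairs replication
#'
#' If an i-motif at a given locus escapes suppression in any one
#' replication cycle with probability `p`, the probability that it
#' impairs replication (and can induce DNA damage) at least once over
#' `cycles` cycles is `1 - (1 - p)^cycles`. Evaluated in log space
#' (`-expm1(cycles * log1p(-p))`) for numerical stability at small `p`.
#'
#' @param p Per-cycle probability of remaining unsuppressed, in `[0, 1]`.
#' @param cycles Positive integer number of replication cycles.
#' @return Probability in `[0, 1]`; vectorized over `p` and `cycles`.
#' @examples
#' impairment_probability(0.05, 25)  # 0.7226, i.e. ~0.72
#' @export
impairment_probability <- function(p, cycles) {
  if (any(p < 0 | p > 1)) abort("`p` must be in [0, 1]")
  if (any(cycles < 1) || any(cycles != round(cycles))) {
    abort("`cycles` must be a positive integer")
  }
  ifelse(p == 1, 1, -expm1(cycles * log1p(-p)))
}

#' Association between in-vitro i-motif stability and deletion frequency
#'
#' Summarizes a length profile (repeat copy number, transitional pH,
#' Tm, observed deletion fraction per locus) with (i) the Spearman rank
#' correlation between transitional pH and deletion fraction (ties
#' mid-ranked) and (ii) a threshold consistency check: whether every
#' locus whose transitional pH exceeds `ph_threshold` shows deletions
#' in 100% of clones. Rows with missing `ph_t` or `deletion_fraction`
#' are dropped from both statistics (with a message). A constant column
#' makes the rank correlation undefined; this is reported explicitly
#' (`rho = NA`, `rho_defined = FALSE`), never silently as 0.
#'
#' @param profile A data frame with at least `ph_t` and
#'   `deletion_fraction` columns (see [tccc_length_profile()]); needs
#'   >= 4 rows.
#' @param ph_threshold Transitional-pH threshold (default 7.0).
#' @return A one-row tibble: `rho`, `rho_defined`,
#'   `threshold_consistency`, `n_used`.
#' @examples
#' profile_association(tccc_length_profile())
#' @export
profile_association <- function(profile, ph_threshold = 7.0) {
  stopifnot(is.data.frame(profile),
            all(c("ph_t", "deletion_fraction") %in% names(profile)))
  if (nrow(profile) < 4) abort("`profile` needs >= 4 rows")
  if (any(profile$deletion_fraction < 0 | profile$deletion_fraction > 1,
          na.rm = TRUE)) {
    abort("`deletion_fraction` must be in [0, 1]")
  }
  ok <- is.finite(profile$ph_t) & is.finite(profile$deletion_fraction)
  if (any(!ok)) {
    message(sum(!ok), " row(s) with missing pH_T or deletion fraction dropped")
  }
  d <- profile[ok, ]
  rho <- if (nrow(d) >= 2 && sd(d$ph_t) > 0 && sd(d$deletion_fraction) > 0) {
    cor(d$ph_t, d$deletion_fraction, method = "spearman")
  } else {
    NA_real_
  }
  above <- d$ph_t > ph_threshold
  tibble(
    rho = rho,
    rho_defined = is.finite(rho),
    threshold_consistency = all(d$deletion_fraction[above] == 1),
    n_used = nrow(d)
  )
}
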