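#' Reference melting and titration summary for the d(TCCC)n length series
#'
#' The published in-vitro summary for d(TCCC)n oligodeoxynucleotides
#' (2.5 uM DNA, 10 mM sodium cacodylate, 100 mM KCl): first-derivative
#' melting (Tm) and annealing (Ta) temperatures with their triplicate
#' standard deviations, the printed hysteresis, and the CD transitional
#' pH with its curve-fit standard error. Rows at buffer pH 6.5 cover
#' n = 4..15; the two rows at buffer pH 5.3 (bisulfite reaction
#' conditions) cover n = 5 and 9 and carry no pH_T.
#'
#' All values are stored verbatim as printed. Note two internal
#' inconsistencies of the printed table at pH 6.5, flagged by
#' [melt_table_consistency()]: for n = 12 the printed hysteresis (9.8)
#' differs from Tm - Ta (9.7) by 0.1 degC (rounding), and for n = 15
#' the printed 16.0 differs from Tm - Ta = 17.0 by a full degree.
#'
#' @param buffer_ph Optional filter: keep only rows at this buffer pH
#'   (6.5 or 5.3).
#' @return A tibble with columns `n`, `buffer_ph`, `tm`, `tm_sd`, `ta`,
#'   `ta_sd`, `hysteresis`, `hysteresis_sd`, `ph_t`, `ph_t_se`.
#' @examples
#' tccc_melt_table(buffer_ph = 6.5)
#' @export
tccc_melt_table <- function(buffer_ph = NULL) {
  tbl <- dplyr::tribble(
    ~n, ~buffer_ph, ~tm, ~tm_sd, ~ta, ~ta_sd, ~hysteresis, ~hysteresis_sd, ~ph_t, ~ph_t_se,
     4, 6.5, 15.6, 1.0, 13.8, 1.2,  1.8, 2.1, 6.6, 0.01,
     5, 6.5, 28.3, 0.6, 26.0, 0.6,  2.4, 1.0, 6.7, 0.04,
     6, 6.5, 31.4, 0.6, 29.2, 0.0,  2.2, 0.6, 6.8, 0.02,
     7, 6.5, 32.8, 1.0, 29.1, 0.0,  3.7, 1.0, 6.8, 0.03,
     8, 6.5, 40.7, 0.6, 30.7, 0.6, 10.0, 0.0, 6.9, 0.01,
     9, 6.5, 40.7, 0.6, 30.3, 0.6, 10.4, 0.6, 7.1, 0.04,
    12, 6.5, 40.2, 0.6, 30.5, 0.0,  9.8, 0.6, 7.2, 0.08,
    14, 6.5, 42.0, 4.0, 30.4, 0.0, 11.6, 4.0, 7.1, 0.07,
    15, 6.5, 40.2, 4.0, 23.2, 2.0, 16.0, 2.0, 7.1, 0.08,
     5, 5.3, 50.2, 3.5, 45.8, 3.5,  4.3, 0.5, NA,  NA,
     9, 5.3, 66.7, 2.0, 62.0, 2.0,  4.6, 0.5, NA,  NA
  )
  if (!is.null(buffer_ph)) tbl <- filter(tbl, .data$buffer_ph == !!buffer_ph)
  tbl
}

#' Internal consistency of the reference melting table
#'
#' Compares each row's printed hysteresis with the recomputed
#' `tm - ta`.
#'
#' @param table A table as returned by [tccc_melt_table()].
#' @param tol Discrepancy (degC) above which a row is flagged.
#' @return The table with added `hysteresis_recomputed`, `discrepancy`
#'   and `flagged` columns.
#' @export
melt_table_consistency <- function(table = tccc_melt_table(), tol = 0.15) {
  table |>
    mutate(
      hysteresis_recomputed = .data$tm - .data$ta,
      discrepancy = abs(.data$hysteresis - .data$hysteresis_recomputed),
      flagged = .data$discrepancy > tol
    )
}

#' Genomic length profile: repeat copy number versus deletion frequency
#'
#' Per-locus summary for five d(TCCC)n-containing genes assayed in the
#' repair-compromised PC3 prostate cancer cell line, pairing the
#' in-vitro stability of the corresponding repeat length (transitional
#' pH and Tm at buffer pH 6.5, where measured) with the fraction of
#' cloned chromosomes carrying a 5'-associated deletion. Fractions are
#' stored as printed where a number was published; values read only
#' from figures carry `provenance = "figure"`. The BCR locus is stored
#' as a deletion count (a single deletion, denominator unpublished)
#' with `deletion_fraction = NA`. No Table entry exists for n = 11
#' (ABL1), so its `ph_t`/`tm` are `NA`.
#'
#' @return A tibble with columns `gene`, `n`, `ph_t`, `tm`,
#'   `deletion_fraction`, `deletion_count`, `provenance`.
#' @examples
#' tccc_length_profile()
#' @export
tccc_length_profile <- function() {
  dplyr::tribble(
    ~gene,      ~n, ~ph_t, ~tm,  ~deletion_fraction, ~deletion_count, ~provenance,
    "HAFA5",     5, 6.7,   28.3, 0,                  0L,              "figure",
    "BCR",       7, 6.8,   32.8, NA,                 1L,              "figure",
    "RACK7",     9, 7.1,   40.7, 1.0,                NA_integer_,     "text",
    "ABL1",     11, NA,    NA,   1.0,                NA_integer_,     "figure",
    "PLA2G2A",  15, 7.1,   40.2, 1.0,                NA_integer_,     "figure"
  )
}
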