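#' Average mass of an oligodeoxynucleotide
#'
#' Sums average residue masses (dA 313.21, dC 289.18, dG 329.21,
#' dT 304.20, dU 290.17 Da) and subtracts 61.96 Da for the free 5'-OH
#' terminus; the 5'-phosphate convention adds 79.98 Da back. Average
#' (not monoisotopic) masses are used because ESI deconvolution of
#' oligos in the 36mer range reports average neutral masses.
#'
#' @param sequence Nucleotide text over `{A,C,G,T,U}` (U = 2'-deoxyuridine).
#' @param terminus `"5prime_OH"` (default, synthetic-oligo convention)
#'   or `"5prime_phosphate"`.
#' @return Neutral average mass in Da.
#' @examples
#' oligo_mass("T")                  # thymidine, 242.24
#' oligo_mass(strrep("TCCC", 9))    # the 36mer, 10483.70
#' @export
oligo_mass <- function(sequence, terminus = c("5prime_OH", "5prime_phosphate")) {
  terminus <- match.arg(terminus)
  if (length(sequence) != 1L || !is.character(sequence) || is.na(sequence) ||
      nchar(sequence) == 0) {
    abort("`sequence` must be a single non-empty string")
  }
  s <- toupper(sequence)
  if (!grepl("^[ACGTU]+$", s)) {
    abort("`sequence` contains a base outside {A,C,G,T,U}")
  }
  residue <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20, U = 290.17)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- sum(residue[chars]) - 61.96
  if (terminus == "5prime_phosphate") m <- m + 79.98
  m
}

#' Assign dU conversion counts to deconvoluted mass peaks
#'
#' Maps each neutral-mass peak onto the conversion ladder
#' `ref_mass + k * delta_m` (k = 0..`n_cytosines`): a peak is assigned
#' the nearest rung `k` if it lies within `tol` Da of it, otherwise it
#' is unassigned. Frequencies are abundance-weighted over assigned
#' peaks. The intact fraction is the share of total abundance at masses
#' `>= ref_mass - tol` (full-length species, converted or not); its
#' complement is carried by sub-reference-mass fragments.
#'
#' @param peaks A data frame with columns `mass_da`, `abundance`.
#' @param ref_mass Reference mass (Da) of the unconverted oligo.
#' @param n_cytosines Maximum conversion count.
#' @param delta_m Mass shift per dC-to-dU conversion (Da); the nominal
#'   "1 Da increase" is 0.984 Da exactly (dU 290.17 - dC 289.18).
#' @param tol Assignment tolerance (Da); must stay below `delta_m / 2`
#'   so assignments are unambiguous.
#' @return A tibble of class `species_table` with columns `k`,
#'   `abundance`, `frequency` (summing to 1 over assigned species) and
#'   attributes `unassigned_fraction`, `intact_fraction`, `ref_mass`.
#' @examples
#' pk <- sim_peak_list(oligo_mass(strrep("TCCC", 9)), 27, 0.33,
#'                     cfg = sim_config(seed = 11))
#' assign_du_counts(pk, oligo_mass(strrep("TCCC", 9)))
#' @export
assign_du_counts <- function(peaks, ref_mass, n_cytosines = 27,
                             delta_m = 0.984, tol = 0.35) {
  stopifnot(is.data.frame(peaks),
            all(c("mass_da", "abundance") %in% names(peaks)))
  if (nrow(peaks) == 0) abort("empty peak list")
  if (delta_m <= 0) abort("`delta_m` must be positive")
  if (tol >= delta_m / 2) abort("`tol` must be below `delta_m` / 2")
  if (any(peaks$mass_da <= 0) || any(!is.finite(peaks$abundance))) {
    abort("peak masses must be positive and abundances finite")
  }
  k <- round((peaks$mass_da - ref_mass) / delta_m)
  resid <- abs(peaks$mass_da - (ref_mass + k * delta_m))
  assigned <- k >= 0 & k <= n_cytosines & resid <= tol
  total <- sum(peaks$abundance)
  assigned_ab <- sum(peaks$abundance[assigned])
  if (assigned_ab == 0) abort("no peak could be assigned to the conversion ladder")
  tab <- tibble(k = as.integer(k[assigned]),
                abundance = peaks$abundance[assigned]) |>
    group_by(.data$k) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    mutate(frequency = .data$abundance / assigned_ab) |>
    arrange(.data$k)
  structure(
    tab,
    unassigned_fraction = 1 - assigned_ab / total,
    intact_fraction = sum(peaks$abundance[peaks$mass_da >= ref_mass - tol]) / total,
    ref_mass = ref_mass,
    class = c("species_table", class(tab))
  )
}

#' @rdname glance-imotifkit
#' @method glance species_table
#' @export
glance.species_table <- function(x, ...) {
  ds <- distribution_stats(x)
  tibble(
    n_species = nrow(x),
    mode_k = ds$mode_k,
    mean_k = ds$mean_k,
    intact_fraction = ds$intact_fraction,
    unassigned_fraction = attr(x, "unassigned_fraction")
  )
}

#' Summary statistics of a conversion-count distribution
#'
#' @param table A `species_table` from [assign_du_counts()].
#' @return A one-row tibble: `mode_k` (k of maximal frequency, ties
#'   broken toward the smaller k), `mean_k` (abundance-weighted) and
#'   `intact_fraction`.
#' @export
distribution_stats <- function(table) {
  stopifnot(inherits(table, "species_table"))
  if (nrow(table) == 0) abort("all peaks were unassigned; no species to summarize")
  i <- which(table$frequency == max(table$frequency))
  tibble(
    mode_k = as.integer(min(table$k[i])),
    mean_k = sum(table$k * table$frequency),
    intact_fraction = attr(table, "intact_fraction")
  )
}
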