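#' Find d(TCCC)n / d(GGGA)n tandem repeat elements
#'
#' Scans a sequence for maximal whole-unit tandem runs of a 4-mer unit on
#' both strands. Runs of the unit itself are reported on the `+` strand;
#' runs of its reverse complement (e.g. GGGA for unit TCCC) are reported
#' as C-rich elements on the `-` strand, with coordinates always on the
#' forward strand of the input. Only whole-unit copies count: a trailing
#' partial copy does not extend a run. `N` terminates a run; any other
#' non-ACGTN character is rejected.
#'
#' Structure-competence flags follow the length thresholds established
#' for this repeat family: G-quadruplex formation of the G-rich strand at
#' `n > 3`, i-motif formation at neutral pH at `n >= 7`, and transitional
#' pH above 7 at `n >= 9`.
#'
#' @param sequence Nucleotide text over `{A,C,G,T,N}`.
#' @param unit Repeat unit on the C-rich strand (default `"TCCC"`).
#' @param min_n Minimum number of whole-unit copies to report.
#' @param seq_id Identifier recorded in the `seq_id` column.
#' @return A tibble with columns `seq_id`, `start`, `end` (0-based
#'   half-open, forward strand), `n`, `unit`, `c_rich_strand`, and
#'   logical flags `g4_competent`, `imotif_neutral_ph`,
#'   `imotif_pht_above7`, ordered by `start`.
#' @examples
#' find_repeat_elements(paste0("AA", strrep("TCCC", 9), "GG"))
#' @export
find_repeat_elements <- function(sequence, unit = "TCCC", min_n = 5,
                                 seq_id = "seq") {
  sequence <- .check_dna(sequence, "sequence")
  unit <- .check_dna(unit, "unit", allow_n = FALSE)
  if (nchar(unit) != 4L) abort("`unit` must be a 4-mer")
  if (min_n < 1) abort("`min_n` must be >= 1")
  rc_unit <- .revcomp(unit)
  scan_one <- function(u, strand) {
    pat <- paste0("(?:", u, "){", min_n, ",}")
    m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "match.length")
    tibble(
      seq_id = seq_id,
      start = as.integer(m) - 1L,
      end = as.integer(m) - 1L + len,
      n = as.integer(len / 4L),
      unit = unit,
      c_rich_strand = strand
    )
  }
  hits <- bind_rows(scan_one(unit, "+"),
                    if (rc_unit != unit) scan_one(rc_unit, "-"))
  if (is.null(hits) || nrow(hits) == 0) {
    hits <- tibble(seq_id = character(), start = integer(), end = integer(),
                   n = integer(), unit = character(),
                   c_rich_strand = character())
  }
  hits |>
    mutate(
      g4_competent = .data$n > 3,
      imotif_neutral_ph = .data$n >= 7,
      imotif_pht_above7 = .data$n >= 9
    ) |>
    arrange(.data$start)
}

#' Annotate maximal cytosine runs and the (4n - 1) length rule
#'
#' Finds all maximal runs of C on the given strand and flags those whose
#' length m satisfies the empirical (4n - 1) rule for near-neutral
#' i-motif folding: m >= 11 and m mod 4 = 3 (lengths 11, 15, 19, 23, ...).
#'
#' @inheritParams find_repeat_elements
#' @return A tibble with columns `start`, `end` (0-based half-open),
#'   `run_length`, `conforms_4n_minus_1`.
#' @examples
#' annotate_c_runs(paste0("AT", strrep("C", 15), "GA"))
#' @export
annotate_c_runs <- function(sequence) {
  sequence <- .check_dna(sequence, "sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(chars) == 0) {
    return(tibble(start = integer(), end = integer(), run_length = integer(),
                  conforms_4n_minus_1 = logical()))
  }
  r <- rle(chars == "C")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble(
    start = starts[keep],
    end = ends[keep],
    run_length = r$lengths[keep]
  ) |>
    mutate(conforms_4n_minus_1 = .data$run_length >= 11 &
             .data$run_length %% 4 == 3)
}

#' Scan a FASTA file for repeat elements
#'
#' Runs [find_repeat_elements()] over every record of a (possibly
#' multi-record) FASTA file and returns BED6-style rows, optionally
#' writing them to a BED file. Output ordering is deterministic:
#' `(seq_id, start)`.
#'
#' @param path Path to a FASTA file.
#' @param unit,min_n Passed to [find_repeat_elements()].
#' @param out Optional output path; when given, a headerless
#'   tab-separated BED6 file is written.
#' @return A tibble with BED6 columns `chrom`, `start`, `end`, `name`
#'   (`unit:n`), `score` (copy count) and `strand` (the C-rich strand).
#' @export
scan_fasta <- function(path, unit = "TCCC", min_n = 5, out = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read FASTA file: ", path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort(paste0("no FASTA records in: ", path))
  ids <- sub("\\s.*$", "", names(seqs))
  bed <- purrr::map_dfr(seq_along(seqs), function(i) {
    find_repeat_elements(as.character(seqs[[i]]), unit = unit, min_n = min_n,
                         seq_id = ids[i])
  })
  bed <- bed |>
    mutate(name = paste0(.data$unit, ":", .data$n), score = .data$n) |>
    select(chrom = "seq_id", "start", "end", "name", "score",
           strand = "c_rich_strand") |>
    arrange(.data$chrom, .data$start)
  if (!is.null(out)) {
    readr::write_tsv(bed, out, col_names = FALSE, progress = FALSE)
  }
  bed
}
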