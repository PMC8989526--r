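#' Build a reference region for bisulfite clone analysis
#'
#' A reference region is the C-rich-strand genomic sequence (5'->3')
#' around one or more d(TCCC)n elements, plus the element table in local
#' 0-based half-open coordinates. All deletion orientation (5' vs 3')
#' downstream is interpreted in this frame.
#'
#' @param sequence C-rich-strand nucleotide text, 5'->3'.
#' @param id Region identifier.
#' @param unit Repeat unit to annotate (default `"TCCC"`).
#' @param min_n Minimum copy count for an annotated element.
#' @param elements Optional pre-computed element tibble (as returned by
#'   [find_repeat_elements()]); scanned from `sequence` when `NULL`.
#' @return An object of class `reference_region`: a list with `id`,
#'   `sequence` and `elements`.
#' @examples
#' ref <- reference_region(paste0(strrep("A", 30), strrep("TCCC", 9),
#'                                strrep("G", 30)))
#' ref$elements
#' @export
reference_region <- function(sequence, id = "region", unit = "TCCC",
                             min_n = 4, elements = NULL) {
  sequence <- .check_dna(sequence, "sequence")
  if (is.null(elements)) {
    elements <- find_repeat_elements(sequence, unit = unit, min_n = min_n,
                                     seq_id = id)
    elements <- filter(elements, .data$c_rich_strand == "+")
  }
  elements <- as_tibble(elements)
  if (nrow(elements) > 0 &&
      (any(elements$start < 0) || any(elements$end > nchar(sequence)))) {
    abort("elements lie outside the reference sequence")
  }
  structure(list(id = id, sequence = sequence, elements = elements),
            class = "reference_region")
}

#' @export
print.reference_region <- function(x, ...) {
  cat("<reference_region> ", x$id, ": ", nchar(x$sequence), " bp, ",
      nrow(x$elements), " element(s)\n", sep = "")
  if (nrow(x$elements) > 0) print(x$elements)
  invisible(x)
}

.default_state_map <- function(region) {
  states <- rep("CG_DUPLEX", nchar(region$sequence))
  for (i in seq_len(nrow(region$elements))) {
    states[(region$elements$start[i] + 1):region$elements$end[i]] <- "CC_PLUS"
  }
  states
}

#' Simulate a set of bisulfite-converted clones
#'
#' Emulates cloned PCR products of a bisulfite-treated native region:
#' each clone starts as the reference, optionally loses one or more
#' planted deletion intervals, and every surviving cytosine is then
#' independently converted to T with the probability of its structural
#' state. Non-C bases are untouched. The planting record is attached as
#' the `"planted"` attribute for oracle-style tests.
#'
#' @param region A [reference_region()].
#' @param n_clones Number of clones to generate.
#' @param rates A [bisulfite_rates()] object.
#' @param state_map Optional character vector, one structural state per
#'   reference position (`"CC_PLUS"`, `"C_PLUS_SS"`, `"CG_DUPLEX"`,
#'   `"C_SS"`). Defaults to `CC_PLUS` inside annotated elements and
#'   `CG_DUPLEX` elsewhere (a folded i-motif embedded in duplex).
#' @param deletions Optional data frame of planted deletions with
#'   columns `clone` (1-based clone index), `start`, `end` (0-based
#'   half-open reference coordinates).
#' @param cfg A [sim_config()].
#' @return A tibble with columns `clone_id`, `sequence`; attribute
#'   `planted` holds the deletion record.
#' @examples
#' ref <- reference_region(paste0(strrep("ATGAC", 8), strrep("TCCC", 9),
#'                                strrep("GATTC", 8)))
#' clones <- sim_clone_set(ref, n_clones = 5, cfg = sim_config(seed = 3))
#' @export
sim_clone_set <- function(region, n_clones, rates = bisulfite_rates(),
                          state_map = NULL, deletions = NULL,
                          cfg = sim_config()) {
  stopifnot(inherits(region, "reference_region"))
  if (n_clones < 1) abort("`n_clones` must be positive")
  L <- nchar(region$sequence)
  state_map <- state_map %||% .default_state_map(region)
  if (length(state_map) != L) {
    abort("`state_map` must have one state per reference position")
  }
  if (!all(state_map %in% c("CC_PLUS", "C_PLUS_SS", "CG_DUPLEX", "C_SS"))) {
    abort("unknown structural state in `state_map`")
  }
  deletions <- if (is.null(deletions)) {
    tibble(clone = integer(), start = integer(), end = integer())
  } else {
    as_tibble(deletions)
  }
  if (nrow(deletions) > 0) {
    if (any(deletions$start < 0) || any(deletions$end > L) ||
        any(deletions$end <= deletions$start)) {
      abort("planted deletion intervals must be non-empty and lie within the region")
    }
    if (any(deletions$clone < 1) || any(deletions$clone > n_clones)) {
      abort("planted deletion `clone` index out of range")
    }
    by_clone <- split(deletions, deletions$clone)
    for (d in by_clone) {
      d <- arrange(d, .data$start)
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
        abort("overlapping planted deletions in one clone")
      }
    }
  }
  ref_chars <- strsplit(region$sequence, "", fixed = TRUE)[[1]]
  p_by_state <- .state_rate(rates)
  p_pos <- ifelse(ref_chars == "C", p_by_state[state_map], 0)
  clones <- withr::with_seed(cfg$seed, {
    purrr::map_chr(seq_len(n_clones), function(i) {
      keep <- rep(TRUE, L)
      del <- deletions[deletions$clone == i, , drop = FALSE]
      for (j in seq_len(nrow(del))) {
        keep[(del$start[j] + 1):del$end[j]] <- FALSE
      }
      converted <- ref_chars
      hit <- runif(L) < p_pos
      converted[hit & ref_chars == "C"] <- "T"
      paste(converted[keep], collapse = "")
    })
  })
  out <- tibble(
    clone_id = sprintf("clone_%03d", seq_len(n_clones)),
    sequence = clones
  )
  attr(out, "planted") <- deletions
  attr(out, "reference_id") <- region$id
  out
}
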