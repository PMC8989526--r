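#' Call C-to-T conversions over aligned clones
#'
#' Tallies reference-cytosine columns across a set of aligned clones.
#' A column (ref C, read T) is a conversion; (ref C, read C) is
#' unconverted; cytosines under read gaps or read A/G are excluded from
#' the denominator and tallied separately. The conversion frequency is
#' converted / (converted + unconverted). Scope is either one element's
#' interval or the whole region.
#'
#' @param alns Alignment tibble from [align_clones()].
#' @param element One-row element (with `start`, `end` local 0-based
#'   coordinates), required for `scope = "element"`.
#' @param scope `"element"` or `"region"`.
#' @return A one-row tibble: `n_converted`, `n_unconverted`,
#'   `n_deleted`, `n_other`, `conversion_frequency`,
#'   `conversions_per_clone_mean`, `n_clones`.
#' @export
call_conversions <- function(alns, element = NULL,
                             scope = c("element", "region")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(alns),
            all(c("ref_aln", "read_aln") %in% names(alns)))
  refs <- unique(gsub("-", "", alns$ref_aln, fixed = TRUE))
  if (length(refs) > 1) abort("aligned clones do not share one reference")
  if (scope == "element") {
    if (is.null(element)) abort("`element` is required for scope = \"element\"")
    s <- element$start[1]
    e <- element$end[1]
  } else {
    s <- 0L
    e <- nchar(refs)
  }
  per_clone <- purrr::pmap_dfr(
    list(alns$ref_aln, alns$read_aln),
    function(ra, da) {
      col <- .alignment_columns(ra, da)
      in_scope <- !is.na(col$ref_pos) & col$ref_pos >= s & col$ref_pos < e &
        col$ref == "C"
      rd <- col$read[in_scope]
      tibble(
        converted = sum(rd == "T"),
        unconverted = sum(rd == "C"),
        deleted = sum(rd == "-"),
        other = sum(!rd %in% c("T", "C", "-"))
      )
    }
  )
  denom <- sum(per_clone$converted) + sum(per_clone$unconverted)
  if (denom == 0) abort("no scorable cytosine columns in scope (zero denominator)")
  tibble(
    n_converted = sum(per_clone$converted),
    n_unconverted = sum(per_clone$unconverted),
    n_deleted = sum(per_clone$deleted),
    n_other = sum(per_clone$other),
    conversion_frequency = sum(per_clone$converted) / denom,
    conversions_per_clone_mean = mean(per_clone$converted),
    n_clones = nrow(alns)
  )
}

.SIDE_LEVELS <- c("UPSTREAM_5P", "OVERLAP_5P", "INTERNAL", "OVERLAP_3P",
                  "DOWNSTREAM_3P", "OUTSIDE")
.FIVE_PRIME_CLASSES <- c("UPSTREAM_5P", "OVERLAP_5P", "INTERNAL")

.classify_side <- function(ref_start, ref_end, s, e, window) {
  if (ref_end <= s && ref_start >= s - window) {
    "UPSTREAM_5P"
  } else if (ref_start < s && ref_end >= s) {
    "OVERLAP_5P"
  } else if (ref_start >= s && ref_end <= e) {
    "INTERNAL"
  } else if (ref_start >= s && ref_start < e && ref_end > e) {
    "OVERLAP_3P"
  } else if (ref_start >= e && ref_end <= e + window) {
    "DOWNSTREAM_3P"
  } else {
    "OUTSIDE"
  }
}

#' Call deletion events relative to a repeat element
#'
#' Every maximal run of read gaps of at least `min_del_len` bp becomes a
#' deletion event with 0-based half-open reference coordinates. Each
#' event is classified against the element interval `[s, e)` on the
#' C-rich strand: entirely in the 5' flank within `window` bp
#' (`UPSTREAM_5P`), starting 5' of the element and reaching into it
#' (`OVERLAP_5P`), contained in the element (`INTERNAL`), starting
#' inside and running past its 3' end (`OVERLAP_3P`), entirely in the 3'
#' flank within `window` bp (`DOWNSTREAM_3P`), or `OUTSIDE`. The
#' deletion frequency is the fraction of clones carrying at least one
#' 5'-associated event (`UPSTREAM_5P`, `OVERLAP_5P` or `INTERNAL`).
#'
#' @inheritParams call_conversions
#' @param window Flank distance (bp) within which an external event is
#'   associated with the element.
#' @param min_del_len Minimum gap run length (bp) to call an event;
#'   1 bp gaps are ambiguous with cloning/sequencing artifacts, so the
#'   default is 2.
#' @return A tibble of class `deletion_calls` with one row per event
#'   (`clone_id`, `ref_start`, `ref_end`, `length`, `side_class`,
#'   `overlap_bp` = bp of the event inside the element) and attributes
#'   `n_clones` and `deletion_frequency`; see [glance.deletion_calls()].
#' @export
call_deletions <- function(alns, element, window = 50, min_del_len = 2) {
  stopifnot(is.data.frame(alns),
            all(c("ref_aln", "read_aln") %in% names(alns)))
  if (window <= 0) abort("`window` must be positive")
  if (min_del_len < 1) abort("`min_del_len` must be >= 1")
  s <- element$start[1]
  e <- element$end[1]
  ref_len <- nchar(gsub("-", "", alns$ref_aln[1], fixed = TRUE))
  if (s < 0 || e > ref_len) abort("element lies outside the reference")
  ids <- alns$clone_id %||% paste0("clone_", seq_len(nrow(alns)))
  events <- purrr::pmap_dfr(
    list(ids, alns$ref_aln, alns$read_aln),
    function(id, ra, da) {
      col <- .alignment_columns(ra, da)
      gap <- col$read == "-" & col$ref != "-"
      if (!any(gap)) return(NULL)
      r <- rle(gap)
      run_end <- cumsum(r$lengths)
      run_start <- run_end - r$lengths + 1L
      keep <- r$values & r$lengths >= min_del_len
      if (!any(keep)) return(NULL)
      tibble(
        clone_id = id,
        ref_start = col$ref_pos[run_start[keep]],
        ref_end = col$ref_pos[run_end[keep]] + 1L
      )
    }
  )
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble(clone_id = character(), ref_start = integer(),
                     ref_end = integer())
  }
  events <- events |>
    mutate(
      length = .data$ref_end - .data$ref_start,
      side_class = purrr::map2_chr(.data$ref_start, .data$ref_end,
                                   .classify_side, s = s, e = e,
                                   window = window),
      overlap_bp = pmax(0L, pmin(.data$ref_end, e) - pmax(.data$ref_start, s))
    )
  carriers <- unique(events$clone_id[events$side_class %in% .FIVE_PRIME_CLASSES])
  structure(
    events,
    n_clones = nrow(alns),
    deletion_frequency = length(carriers) / nrow(alns),
    element = list(start = s, end = e, window = window),
    class = c("deletion_calls", class(events))
  )
}

#' Deletion frequency of a call set
#'
#' @param calls A [call_deletions()] result.
#' @return The fraction of clones carrying a 5'-associated deletion.
#' @export
deletion_frequency <- function(calls) {
  stopifnot(inherits(calls, "deletion_calls"))
  attr(calls, "deletion_frequency")
}

#' @rdname glance-imotifkit
#' @method glance deletion_calls
#' @export
glance.deletion_calls <- function(x, ...) {
  tibble(
    n_clones = attr(x, "n_clones"),
    n_events = nrow(x),
    deletion_frequency = attr(x, "deletion_frequency")
  )
}

#' Per-element conversion and deletion report for a region
#'
#' Aligns a clone set to a reference region and aggregates, for every
#' annotated element, the C-to-T conversion statistics (element scope)
#' and the 5'-associated deletion frequency, plus region-scoped mean
#' conversions per clone.
#'
#' @param reference A [reference_region()].
#' @param clones Clone tibble or named character vector (see
#'   [align_clones()]).
#' @param window,min_del_len Passed to [call_deletions()].
#' @param mode Alignment mode, see [align_clones()].
#' @return A tibble with one row per element: `element_id`, `n`,
#'   `start`, `end`, `n_clones`, `conversion_frequency`,
#'   `conversions_per_clone_element`, `conversions_per_clone_region`,
#'   `deletion_frequency`, `n_deletion_events`. The alignment tibble is
#'   attached as attribute `alignments`.
#' @export
region_report <- function(reference, clones, window = 50, min_del_len = 2,
                          mode = "bisulfite") {
  stopifnot(inherits(reference, "reference_region"))
  if (nrow(reference$elements) == 0) abort("reference has no annotated elements")
  alns <- align_clones(reference, clones, mode = mode)
  region_conv <- call_conversions(alns, scope = "region")
  rows <- purrr::map_dfr(seq_len(nrow(reference$elements)), function(i) {
    el <- reference$elements[i, ]
    conv <- call_conversions(alns, el, scope = "element")
    dels <- call_deletions(alns, el, window = window,
                           min_del_len = min_del_len)
    tibble(
      element_id = paste0(reference$id, ":", el$unit, "x", el$n),
      n = el$n, start = el$start, end = el$end,
      n_clones = nrow(alns),
      conversion_frequency = conv$conversion_frequency,
      conversions_per_clone_element = conv$conversions_per_clone_mean,
      conversions_per_clone_region = region_conv$conversions_per_clone_mean,
      deletion_frequency = attr(dels, "deletion_frequency"),
      n_deletion_events = nrow(dels)
    )
  })
  attr(rows, "alignments") <- alns
  rows
}

#' Render aligned clones as fixed-width text
#'
#' Produces a plain-text alignment panel: the reference on top, then one
#' line per clone in which matches are `.`, converted cytosines (ref C,
#' read T) are `t`, deletions are `-`, and other mismatches show the
#' read base.
#'
#' @param alns Alignment tibble from [align_clones()].
#' @return A character vector of lines (print with [writeLines()]).
#' @export
render_alignment <- function(alns) {
  stopifnot(is.data.frame(alns), nrow(alns) > 0)
  ref_gapped <- alns$ref_aln[1]
  lines <- purrr::pmap_chr(
    list(alns$ref_aln, alns$read_aln),
    function(ra, da) {
      col <- .alignment_columns(ra, da)
      out <- ifelse(col$read == col$ref, ".",
               ifelse(col$read == "-", "-",
                 ifelse(col$ref == "C" & col$read == "T", "t", col$read)))
      paste(out, collapse = "")
    }
  )
  ids <- alns$clone_id %||% paste0("clone_", seq_len(nrow(alns)))
  w <- max(nchar(c("Ref.", ids)))
  c(
    sprintf("%-*s %s", w, "Ref.", ref_gapped),
    sprintf("%-*s %s", w, ids, lines)
  )
}
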