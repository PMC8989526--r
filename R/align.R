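#' Bisulfite-aware substitution matrix
#'
#' Scoring matrix for clone-to-reference global alignment. In bisulfite
#' mode the asymmetric cell (reference C, read T) scores as a full
#' match, so chemical C-to-T conversions are never forced into gaps or
#' penalized as mismatches.
#'
#' @param match,mismatch Match and mismatch scores.
#' @param mode `"bisulfite"` or `"standard"`.
#' @return A 5x5 numeric matrix over `A,C,G,T,N` with rows indexed by
#'   the read base and columns by the reference base.
#' @export
bisulfite_submat <- function(match = 1, mismatch = -2,
                             mode = c("bisulfite", "standard")) {
  mode <- match.arg(mode)
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(read = bases, ref = bases))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  if (mode == "bisulfite") m["T", "C"] <- match  # converted cytosine
  m
}

#' Align bisulfite clones to a reference region
#'
#' Global (Needleman-Wunsch) alignment with affine gap penalties of each
#' clone against the C-rich-strand reference, end gaps penalized (clones
#' are full-length PCR products). In `"bisulfite"` mode a read T under a
#' reference C scores as a match. Before alignment each clone is
#' orientation-checked: it is aligned both as given and
#' reverse-complemented, and the higher-scoring orientation is kept.
#' Traceback is deterministic (Biostrings), so identical inputs give
#' identical alignments.
#'
#' @param reference A [reference_region()] or a plain reference
#'   sequence string.
#' @param clones A data frame with columns `clone_id` and `sequence`
#'   (e.g. from [sim_clone_set()] or read from FASTA), or a (named)
#'   character vector.
#' @param mode `"bisulfite"` (default) or `"standard"`.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters; gap
#'   penalties are positive costs.
#' @param check_orientation Try the reverse complement of each clone and
#'   keep the better-scoring orientation.
#' @return A tibble with one row per clone: `clone_id`, `ref_aln` and
#'   `read_aln` (equal-length gapped strings), `score`, `flipped`.
#'   Degapping `ref_aln` always reproduces the reference, and degapping
#'   `read_aln` the (possibly reverse-complemented) clone.
#' @examples
#' ref <- reference_region(paste0(strrep("ATGAC", 6), strrep("TCCC", 5),
#'                                strrep("GATTC", 6)))
#' align_clones(ref, c(c1 = ref$sequence))
#' @export
align_clones <- function(reference, clones, mode = c("bisulfite", "standard"),
                         match = 1, mismatch = -2, gap_open = 5,
                         gap_extend = 1, check_orientation = TRUE) {
  mode <- match.arg(mode)
  ref_seq <- if (inherits(reference, "reference_region")) {
    reference$sequence
  } else {
    .check_dna(reference, "reference")
  }
  if (is.data.frame(clones)) {
    ids <- clones$clone_id %||% paste0("clone_", seq_len(nrow(clones)))
    seqs <- clones$sequence
  } else {
    seqs <- unname(clones)
    ids <- names(clones) %||% paste0("clone_", seq_along(clones))
    if (any(ids == "")) ids[ids == ""] <- paste0("clone_", which(ids == ""))
  }
  if (length(seqs) == 0) abort("no clones supplied")
  seqs <- vapply(seqs, .check_dna, character(1), what = "clone")
  if (any(nchar(seqs) == 0)) abort("empty clone sequence")
  ratio <- nchar(seqs) / nchar(ref_seq)
  if (any(ratio < 0.3 | ratio > 1.2)) {
    abort("clone length outside [0.3, 1.2] x reference length")
  }
  sm <- bisulfite_submat(match, mismatch, mode)
  subject <- Biostrings::DNAString(ref_seq)
  do_align <- function(x) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(x), subject,
      type = "global", substitutionMatrix = sm,
      gapOpening = gap_open, gapExtension = gap_extend
    )
  }
  fwd <- do_align(seqs)
  flipped <- rep(FALSE, length(seqs))
  best <- fwd
  if (check_orientation) {
    rc <- vapply(seqs, .revcomp, character(1))
    rev <- do_align(rc)
    flipped <- Biostrings::score(rev) > Biostrings::score(fwd)
    if (any(flipped)) {
      # re-run per orientation to keep a single aligned object
      keep_seqs <- ifelse(flipped, rc, seqs)
      best <- do_align(keep_seqs)
    }
  }
  tibble(
    clone_id = unname(ids),
    ref_aln = unname(as.character(Biostrings::alignedSubject(best))),
    read_aln = unname(as.character(Biostrings::alignedPattern(best))),
    score = unname(Biostrings::score(best)),
    flipped = unname(flipped)
  )
}

#' @rdname align_clones
#' @param clone A single clone sequence.
#' @param ... Passed to [align_clones()].
#' @export
align_clone <- function(reference, clone, ...) {
  align_clones(reference, c(clone_1 = clone), ...)
}

# split an alignment row into per-column reference coordinates;
# returns list(ref = chars, read = chars, ref_pos = 0-based position of the
# reference base in each column, NA for reference-gap columns)
.alignment_columns <- function(ref_aln, read_aln) {
  rc <- strsplit(ref_aln, "", fixed = TRUE)[[1]]
  dc <- strsplit(read_aln, "", fixed = TRUE)[[1]]
  if (length(rc) != length(dc)) abort("corrupt alignment: unequal row lengths")
  pos <- cumsum(rc != "-") - 1L
  pos[rc == "-"] <- NA_integer_
  list(ref = rc, read = dc, ref_pos = pos)
}
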