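# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: the scanner oracle enumerates unit multiples by
# direct substring comparison, the derivative oracle differentiates on a
# dense grid, and the Spearman oracle ranks by hand.

# brute-force tandem-repeat scan: check every start position for >= min_n
# consecutive whole copies of `unit`, keep maximal runs only
oracle_scan_one_strand <- function(sequence, unit, min_n) {
  L <- nchar(sequence)
  u <- nchar(unit)
  if (L < u * min_n) {
    return(data.frame(start = integer(), end = integer(), n = integer()))
  }
  is_unit_at <- vapply(seq_len(L - u + 1L), function(i) {
    substr(sequence, i, i + u - 1L) == unit
  }, logical(1))
  out <- list()
  i <- 1L
  while (i <= length(is_unit_at)) {
    if (is_unit_at[i]) {
      k <- 0L
      while (i + k * u <= length(is_unit_at) && is_unit_at[i + k * u]) {
        k <- k + 1L
      }
      if (k >= min_n) {
        out[[length(out) + 1L]] <- data.frame(start = i - 1L,
                                              end = i - 1L + k * u, n = k)
      }
      i <- i + k * u  # skip past the run: maximality
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) {
    data.frame(start = integer(), end = integer(), n = integer())
  } else {
    do.call(rbind, out)
  }
}

oracle_scan <- function(sequence, unit = "TCCC", min_n = 5) {
  rc_unit <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(unit))
  )
  fwd <- oracle_scan_one_strand(sequence, unit, min_n)
  fwd$c_rich_strand <- rep("+", nrow(fwd))
  rev <- oracle_scan_one_strand(sequence, rc_unit, min_n)
  rev$c_rich_strand <- rep("-", nrow(rev))
  out <- rbind(fwd, rev)
  out[order(out$start), , drop = FALSE]
}

# dense numerical derivative-extremum oracle for melting curves
oracle_derivative_extremum <- function(f, lo, hi, step = 0.001) {
  tt <- seq(lo, hi, by = step)
  y <- f(tt)
  d <- abs(diff(y) / diff(tt))
  mid <- tt[-1] - step / 2
  mid[which.max(d)]
}

# random DNA string
random_dna <- function(n, seed) {
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
}

# Spearman rank correlation from first principles (mid-ranked ties)
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# reference region with one centered TCCC element on fixed (non-random)
# flanks free of C runs, handy for exact alignment expectations
toy_region <- function(n_unit = 5, flank = 40, seed = NULL) {
  if (is.null(seed)) {
    fl <- strrep("ATGA", flank %/% 4)
    fr <- strrep("GATT", flank %/% 4)
  } else {
    fl <- random_dna(flank, seed)
    fr <- random_dna(flank, seed + 1L)
  }
  reference_region(paste0(fl, strrep("TCCC", n_unit), fr),
                   id = paste0("toy", n_unit))
}
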