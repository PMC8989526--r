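test_that("alignment round-trips: degapped rows reproduce the inputs", {
  ref <- toy_region(5, flank = 40, seed = 101)
  cl <- sim_clone_set(ref, 6,
                      deletions = tibble::tibble(clone = c(2L, 4L),
                                                 start = c(20L, 50L),
                                                 end = c(30L, 58L)),
                      cfg = sim_config(9))
  alns <- align_clones(ref, cl)
  expect_equal(nrow(alns), 6)
  for (i in seq_len(nrow(alns))) {
    expect_identical(gsub("-", "", alns$ref_aln[i], fixed = TRUE),
                     ref$sequence)
    expect_identical(gsub("-", "", alns$read_aln[i], fixed = TRUE),
                     cl$sequence[i])
    expect_equal(nchar(alns$ref_aln[i]), nchar(alns$read_aln[i]))
  }
})

test_that("identity and fully converted clones align without gaps", {
  ref <- toy_region(5)
  alns <- align_clones(ref, c(same = ref$sequence))
  expect_false(grepl("-", alns$ref_aln, fixed = TRUE))
  expect_false(grepl("-", alns$read_aln, fixed = TRUE))
  conv <- gsub("C", "T", ref$sequence)
  a2 <- align_clones(ref, c(conv = conv))
  expect_false(grepl("-", a2$read_aln, fixed = TRUE))
  # bisulfite scoring: the fully converted clone scores like the identity
  expect_equal(a2$score, alns$score)
  # standard mode penalizes the conversions instead
  a3 <- align_clones(ref, c(conv = conv), mode = "standard",
                     check_orientation = FALSE)
  expect_lt(a3$score, a2$score)
  expect_error(align_clones(ref, c(x = "")), "empty|length")
  expect_error(align_clones(ref, c(x = substr(ref$sequence, 1, 10))),
               "0.3")
})

test_that("bisulfite matrix never scores (ref C, read T) worse than (C, C)", {
  m <- bisulfite_submat()
  expect_gte(m["T", "C"], m["C", "C"])
  expect_lt(bisulfite_submat(mode = "standard")["T", "C"], m["C", "C"])
})

test_that("reverse-complemented clones are flipped back before analysis", {
  ref <- toy_region(5, flank = 40, seed = 55)
  cl <- sim_clone_set(ref, 1, cfg = sim_config(5))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cl$sequence[1])
  ))
  a <- align_clones(ref, c(fwd = cl$sequence[1], rev = rc))
  expect_equal(a$flipped, c(FALSE, TRUE))
  expect_equal(a$score[1], a$score[2])
  expect_identical(gsub("-", "", a$read_aln[2], fixed = TRUE),
                   cl$sequence[1])
})

test_that("conversion calling matches hand-counted tallies on a toy set", {
  # reference with 4 Cs; three manual clones
  ref <- reference_region("ATCGACGTCAGTCA", id = "toy", min_n = 99,
                          elements = tibble::tibble(start = 0L, end = 14L,
                                                    n = 1L, unit = "TCCC"))
  clones <- c(
    c1 = "ATCGACGTCAGTCA",  # no conversions: 4 unconverted
    c2 = "ATTGATGTCAGTCA",  # C3,C6 -> T: 2 converted, 2 unconverted
    c3 = "ATTGATGTTAGTTA"   # all 4 -> T
  )
  alns <- align_clones(ref, clones)
  st <- call_conversions(alns, scope = "region")
  expect_equal(st$n_converted, 6)
  expect_equal(st$n_unconverted, 6)
  expect_equal(st$conversion_frequency, 0.5)
  expect_equal(st$conversions_per_clone_mean, 2)
  expect_equal(st$n_clones, 3)
})

test_that("conversion frequency is recovered and zero/full cases are exact", {
  ref <- toy_region(9, flank = 40, seed = 77)
  el <- ref$elements[ref$elements$n == 9, ]
  p <- 0.374
  cl <- sim_clone_set(ref, 150, rates = bisulfite_rates(p_cc_plus = p),
                      cfg = sim_config(7))
  st <- call_conversions(align_clones(ref, cl), el)
  se <- sqrt(p * (1 - p) / (150 * 27))
  expect_lt(abs(st$conversion_frequency - p), 3 * se)
  # no conversions -> 0; all converted -> 1
  r0 <- suppressWarnings(bisulfite_rates(0, 0, 0, 0))
  st0 <- call_conversions(align_clones(ref, sim_clone_set(ref, 5, rates = r0)),
                          el)
  expect_equal(st0$conversion_frequency, 0)
  r1 <- suppressWarnings(bisulfite_rates(1, 1, 1, 1))
  st1 <- call_conversions(align_clones(ref, sim_clone_set(ref, 5, rates = r1)),
                          el)
  expect_equal(st1$conversion_frequency, 1)
})

test_that("conversion estimator is unbiased over seeds", {
  ref <- toy_region(9, flank = 24)
  el <- ref$elements[1, ]
  p <- 0.35
  est <- purrr::map_dbl(1:30, function(s) {
    cl <- sim_clone_set(ref, 30, rates = bisulfite_rates(p_cc_plus = p),
                        cfg = sim_config(s))
    call_conversions(align_clones(ref, cl), el)$conversion_frequency
  })
  n_draws <- 30 * 30 * 27
  expect_lt(abs(mean(est) - p), 3 * sqrt(p * (1 - p) / n_draws))
})

test_that("deletion events are called at planted coordinates and classified", {
  ref <- toy_region(5, flank = 40, seed = 31)
  el <- ref$elements[1, ]
  s <- el$start
  e <- el$end
  dels <- tibble::tibble(clone = 1:5, start = s - 12L, end = s - 4L)
  cl <- sim_clone_set(ref, 27, deletions = dels, cfg = sim_config(3))
  alns <- align_clones(ref, cl)
  calls <- call_deletions(alns, el, window = 50, min_del_len = 2)
  expect_equal(nrow(calls), 5)
  expect_true(all(calls$side_class == "UPSTREAM_5P"))
  expect_true(all(calls$length == 8))
  # called placement may differ from the planted one only by a shift that is
  # equivalent under bisulfite scoring (a C may align under a converted T),
  # so compare the excised references with C and T collapsed
  excise <- function(x, a, b) paste0(substr(x, 1, a), substr(x, b + 1, nchar(x)))
  planted_seq <- gsub("C", "T", excise(ref$sequence, s - 12, s - 4))
  for (i in seq_len(nrow(calls))) {
    expect_identical(
      gsub("C", "T", excise(ref$sequence, calls$ref_start[i], calls$ref_end[i])),
      planted_seq
    )
  }
  expect_equal(attr(calls, "deletion_frequency"), 5 / 27)
  expect_equal(glance(calls)$deletion_frequency, 5 / 27)
  expect_equal(deletion_frequency(calls), 5 / 27)
})

test_that("side classes follow the interval rules and the window moves only the flanks", {
  s <- 50L; e <- 70L
  cases <- list(
    list(30L, 40L, "UPSTREAM_5P"),
    list(44L, 52L, "OVERLAP_5P"),
    list(40L, 90L, "OVERLAP_5P"),   # spans the whole element: 5' overlap wins
    list(54L, 60L, "INTERNAL"),
    list(60L, 80L, "OVERLAP_3P"),
    list(75L, 85L, "DOWNSTREAM_3P"),
    list(150L, 160L, "OUTSIDE")
  )
  for (cs in cases) {
    expect_equal(
      imotifkit:::.classify_side(cs[[1]], cs[[2]], s, e, window = 50),
      cs[[3]],
      info = paste(cs[[1]], cs[[2]])
    )
  }
  # shrinking the window only moves flank events to OUTSIDE
  expect_equal(imotifkit:::.classify_side(30L, 40L, s, e, window = 5),
               "OUTSIDE")
  expect_equal(imotifkit:::.classify_side(75L, 85L, s, e, window = 5),
               "OUTSIDE")
  expect_equal(imotifkit:::.classify_side(54L, 60L, s, e, window = 5),
               "INTERNAL")
})

test_that("deletions overlapping the element 5' boundary are counted at full frequency", {
  ref <- toy_region(9, flank = 40, seed = 41)
  el <- ref$elements[1, ]
  s <- el$start
  dels <- tibble::tibble(clone = 1:27, start = s - 6L, end = s + 6L)
  cl <- sim_clone_set(ref, 27, deletions = dels, cfg = sim_config(8))
  calls <- call_deletions(align_clones(ref, cl), el)
  expect_equal(attr(calls, "deletion_frequency"), 1.0)
  expect_true(all(calls$side_class %in% c("OVERLAP_5P", "INTERNAL",
                                          "UPSTREAM_5P")))
  expect_true(all(calls$overlap_bp > 0 | calls$side_class == "UPSTREAM_5P"))
  # an event entirely 3' of the element does not count
  dels3 <- tibble::tibble(clone = 1L, start = el$end + 10L, end = el$end + 20L)
  cl3 <- sim_clone_set(ref, 4, deletions = dels3, cfg = sim_config(9))
  calls3 <- call_deletions(align_clones(ref, cl3), el)
  expect_equal(calls3$side_class, "DOWNSTREAM_3P")
  expect_equal(attr(calls3, "deletion_frequency"), 0)
})

test_that("region report orders conversion and deletion by repeat length", {
  # one region holding both a weak (n=5) and a strong (n=9) element
  left <- random_dna(40, 201)
  mid <- random_dna(60, 202)
  right <- random_dna(40, 203)
  seqr <- paste0(left, strrep("TCCC", 5), mid, strrep("TCCC", 9), right)
  ref <- reference_region(seqr, id = "RACK7like", min_n = 5)
  expect_equal(ref$elements$n, c(5L, 9L))
  s9 <- ref$elements$start[2]
  # state map: n=5 element partially duplexed (low rate), n=9 i-motif
  states <- rep("CG_DUPLEX", nchar(seqr))
  states[(s9 + 1):(s9 + 36)] <- "CC_PLUS"
  dels <- tibble::tibble(clone = 1:12, start = s9 - 10L, end = s9 + 2L)
  cl <- sim_clone_set(ref, 20, state_map = states, deletions = dels,
                      cfg = sim_config(13))
  rep_tbl <- region_report(ref, cl)
  expect_equal(nrow(rep_tbl), 2)
  r5 <- rep_tbl[rep_tbl$n == 5, ]
  r9 <- rep_tbl[rep_tbl$n == 9, ]
  expect_gt(r9$conversion_frequency, r5$conversion_frequency)
  expect_gt(r9$deletion_frequency, r5$deletion_frequency)
  expect_equal(r9$deletion_frequency, 12 / 20)
  # clones identical to the reference give an all-zero report
  null_rep <- region_report(ref, c(a = seqr, b = seqr))
  expect_true(all(null_rep$conversion_frequency == 0))
  expect_true(all(null_rep$deletion_frequency == 0))
  # the text rendering marks conversions and deletions
  lines <- render_alignment(attr(rep_tbl, "alignments"))
  expect_equal(length(lines), 21)
  expect_true(any(grepl("t", lines[-1], fixed = TRUE)))
  expect_true(any(grepl("-", lines[-1], fixed = TRUE)))
})
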