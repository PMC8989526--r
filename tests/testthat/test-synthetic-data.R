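test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 42, noise_sd = 0.02, n_replicates = 2)
  expect_identical(sim_melt_curve(40, cfg = cfg), sim_melt_curve(40, cfg = cfg))
  expect_identical(sim_titration(7.0, cfg = cfg), sim_titration(7.0, cfg = cfg))
  expect_identical(sim_peak_list(1000, 10, 0.3, cfg = cfg),
                   sim_peak_list(1000, 10, 0.3, cfg = cfg))
  expect_identical(as.character(sim_genome(500, cfg = cfg)),
                   as.character(sim_genome(500, cfg = cfg)))
  ref <- toy_region(5)
  expect_identical(sim_clone_set(ref, 5, cfg = cfg),
                   sim_clone_set(ref, 5, cfg = cfg))
  # and a different seed changes the noise
  expect_false(identical(sim_titration(7.0, cfg = cfg),
                         sim_titration(7.0, cfg = sim_config(43, 0.02, 2))))
})

test_that("noise-free melt curve is a symmetric sigmoid with midpoint at tm", {
  cv <- sim_melt_curve(tm = 40, grid = seq(10, 70, 1), dH = -40)
  # signal midway between baselines exactly at tm
  mid <- (0.95 + 0.60) / 2
  expect_equal(cv$signal[cv$temperature_C == 40], mid, tolerance = 1e-12)
  # symmetry about tm
  lo <- cv$signal[cv$temperature_C == 30]
  hi <- cv$signal[cv$temperature_C == 50]
  expect_equal(lo - mid, mid - hi, tolerance = 1e-10)
  # unfolded fraction: 0.5 at tm, -> 1 hot, -> 0 cold, increasing
  a <- unfolded_fraction(seq(0, 100, 5), tm = 40, dH = -40)
  expect_true(all(diff(a) > 0))
  expect_equal(unfolded_fraction(40, 40), 0.5)
  # exact van't Hoff form keeps the same midpoint and orientation
  av <- unfolded_fraction(c(20, 40, 90), 40, dH = -40, model = "vant_hoff")
  expect_equal(av[2], 0.5)
  expect_true(av[1] < 0.5 && av[3] > 0.5)
})

test_that("melt generator warns when tm lies outside the grid", {
  expect_warning(sim_melt_curve(tm = 150, grid = seq(4, 95, 1)),
                 "outside the temperature grid")
  expect_error(sim_melt_curve(tm = 40, grid = numeric()), "empty")
  expect_error(sim_melt_curve(tm = 40, dH = 10), "negative")
})

test_that("titration generator hits the sigmoid midpoint and limits", {
  cv <- sim_titration(ph_t = 7.0, theta_folded = 8, theta_unfolded = 0.5,
                      grid = seq(5, 8, 0.25))
  expect_equal(cv$ellipticity_mdeg[cv$ph == 7.0], (8 + 0.5) / 2)
  # folded baseline attained at low pH
  expect_gt(cv$ellipticity_mdeg[cv$ph == 5.0], cv$ellipticity_mdeg[cv$ph == 8.0])
  # steep slope limit approaches a step between baselines
  steep <- sim_titration(ph_t = 6.5, hill = 80, grid = seq(5, 8, 0.25))
  below <- steep$ellipticity_mdeg[steep$ph <= 6.25]
  above <- steep$ellipticity_mdeg[steep$ph >= 6.75]
  expect_true(all(abs(below - 8) < 1e-8))
  expect_true(all(abs(above - 0.5) < 1e-8))
  expect_error(sim_titration(7, theta_folded = 1, theta_unfolded = 1),
               "degenerate")
  expect_error(sim_titration(7, grid = c(3.5, 5, 7)), "\\[4, 9\\]")
})

test_that("clone generator plants deletions and converts per state", {
  ref <- toy_region(5)
  # degenerate rates break the reactivity ordering, hence the warnings
  expect_warning(r0 <- bisulfite_rates(0, 0, 0, 0), "ordering")
  expect_warning(r1 <- bisulfite_rates(1, 1, 1, 1), "ordering")
  # all rates zero, no deletions -> clones identical to reference
  cl0 <- sim_clone_set(ref, 3, rates = r0)
  expect_true(all(cl0$sequence == ref$sequence))
  # all rates one -> every C becomes T
  cl1 <- sim_clone_set(ref, 3, rates = r1)
  expect_identical(unique(cl1$sequence), gsub("C", "T", ref$sequence))
  # planted deletion excised exactly
  s <- ref$elements$start[1]
  dels <- tibble::tibble(clone = 1L, start = s - 12L, end = s - 4L)
  cl <- sim_clone_set(ref, 2, rates = r0, deletions = dels,
                      cfg = sim_config(1))
  expect_equal(nchar(cl$sequence[1]), nchar(ref$sequence) - 8L)
  expect_equal(nchar(cl$sequence[2]), nchar(ref$sequence))
  expected <- paste0(substr(ref$sequence, 1, s - 12),
                     substr(ref$sequence, s - 3, nchar(ref$sequence)))
  expect_identical(cl$sequence[1], expected)
  # overlapping planted deletions rejected
  bad <- tibble::tibble(clone = c(1L, 1L), start = c(10L, 14L),
                        end = c(18L, 20L))
  expect_error(sim_clone_set(ref, 2, rates = r0, deletions = bad),
               "overlapping")
})

test_that("clone conversion counts match the binomial expectation", {
  # >= 10^4 Bernoulli draws on element cytosines; estimator within 3 SE
  ref <- toy_region(9, flank = 40)
  p <- 0.374
  n_clones <- 400  # 400 x 27 = 10800 draws
  cl <- sim_clone_set(ref, n_clones, rates = bisulfite_rates(p_cc_plus = p),
                      cfg = sim_config(7))
  s <- ref$elements$start[1]
  e <- ref$elements$end[1]
  n_conv <- sum(vapply(cl$sequence, function(x) {
    el <- substr(x, s + 1, e)
    sum(strsplit(el, "")[[1]] == "T") - 9L  # subtract the 9 unit Ts
  }, numeric(1)))
  n_draws <- n_clones * 27
  se <- sqrt(p * (1 - p) / n_draws)
  expect_lt(abs(n_conv / n_draws - p), 3 * se)
})

test_that("peak-list generator respects the binomial mode and mass ordering", {
  rm9 <- oligo_mass(strrep("TCCC", 9))
  pk <- sim_peak_list(rm9, 27, p_convert = 0, n_molecules = 100,
                      cfg = sim_config(1))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$mass_da, rm9)
  pk1 <- sim_peak_list(rm9, 27, p_convert = 1, n_molecules = 100,
                       cfg = sim_config(1))
  expect_equal(pk1$mass_da, rm9 + 27 * 0.984)
  # all full-length species >= ref mass; fragments below
  pkf <- sim_peak_list(rm9, 27, p_convert = 0.33, n_molecules = 2000,
                       fragment_fraction = 0.1, cfg = sim_config(2))
  expect_true(all(pkf$mass_da >= rm9 - 1e-9 | pkf$mass_da < rm9 * 0.9))
  frag_share <- sum(pkf$abundance[pkf$mass_da < rm9]) / sum(pkf$abundance)
  expect_equal(frag_share, 0.1, tolerance = 1e-9)
  expect_error(sim_peak_list(rm9, 27, 0.33, fragment_fraction = 1),
               "fragment_fraction")
})

test_that("genome generator plants exact repeats and rejects overlap", {
  planted <- tibble::tibble(position = c(100L, 300L),
                            unit = c("TCCC", "GGGA"), n = c(9L, 5L))
  g <- sim_genome(1000, planted, cfg = sim_config(5))
  gs <- as.character(g)  # drop the planting attribute for comparison
  expect_identical(substr(gs, 101, 136), strrep("TCCC", 9))
  expect_identical(substr(gs, 301, 320), strrep("GGGA", 5))
  expect_identical(attr(g, "planted")$position, c(100L, 300L))
  bad <- tibble::tibble(position = c(100L, 110L), unit = c("TCCC", "TCCC"),
                        n = c(9L, 9L))
  expect_error(sim_genome(1000, bad), "overlap")
  expect_error(sim_genome(100, tibble::tibble(position = 90L, unit = "TCCC",
                                              n = 9L)),
               "outside")
})
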