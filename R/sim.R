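#' Simulation configuration
#'
#' A small container carrying the seed and noise settings shared by all
#' synthetic-data generators. Every generator consumes the seed through an
#' isolated RNG scope ([withr::with_seed()]), so two calls with the same
#' configuration and parameters produce byte-identical output and the
#' caller's RNG state is never touched.
#'
#' @param seed Integer seed for the generator's private RNG stream.
#' @param noise_sd Gaussian noise standard deviation, expressed as a
#'   fraction of the signal amplitude (0 = noise-free).
#' @param n_replicates Number of replicate series to generate per call.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(seed = 42, noise_sd = 0.02, n_replicates = 3)
#' @export
sim_config <- function(seed = 1L, noise_sd = 0, n_replicates = 1L) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    abort("`noise_sd` must be a single nonnegative number")
  }
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L || n_replicates < 1) {
    abort("`n_replicates` must be a positive integer")
  }
  structure(
    list(seed = as.integer(seed), noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates)),
    class = "sim_config"
  )
}

#' Per-state bisulfite conversion probabilities
#'
#' Conversion probabilities for a cytosine depending on its structural
#' state during the bisulfite reaction. The defaults encode the frontier
#' orbital reactivity ordering dC+ > C:C+ >> C:G > dC: a protonated
#' single-stranded cytosine is most reactive, a cytosine in a
#' hemiprotonated C:C+ i-motif pair nearly as reactive, an unprotonated
#' single-stranded cytosine weakly reactive and a Watson-Crick paired
#' cytosine essentially inert. The default magnitudes are chosen so that
#' an i-motif element converts on the scale observed for d(TCCC)9 in
#' native genomic DNA; all four rates are user-overridable.
#'
#' @param p_cc_plus Conversion probability for a cytosine in a C:C+
#'   i-motif base pair.
#' @param p_c_plus_ss Probability for a protonated single-stranded
#'   cytosine.
#' @param p_cg_duplex Probability for a Watson-Crick paired cytosine.
#' @param p_c_ss Probability for an unprotonated single-stranded cytosine.
#' @return An object of class `bisulfite_rates` (a named list).
#' @examples
#' bisulfite_rates()
#' bisulfite_rates(p_cc_plus = 0.374)
#' @export
bisulfite_rates <- function(p_cc_plus = 0.35, p_c_plus_ss = 0.45,
                            p_cg_duplex = 0.01, p_c_ss = 0.05) {
  p <- c(p_cc_plus = p_cc_plus, p_c_plus_ss = p_c_plus_ss,
         p_cg_duplex = p_cg_duplex, p_c_ss = p_c_ss)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("all bisulfite rates must be probabilities in [0, 1]")
  }
  if (!(p_c_plus_ss >= p_cc_plus && p_cc_plus > p_c_ss && p_c_ss >= p_cg_duplex)) {
    warn("rates do not follow the reactivity ordering dC+ >= C:C+ > dC >= C:G")
  }
  structure(as.list(p), class = "bisulfite_rates")
}

.state_rate <- function(rates) {
  c(CC_PLUS = rates$p_cc_plus, C_PLUS_SS = rates$p_c_plus_ss,
    CG_DUPLEX = rates$p_cg_duplex, C_SS = rates$p_c_ss)
}

#' Simulate a UV melting or annealing curve
#'
#' Generates absorbance-at-295 nm temperature ramps from a two-state
#' (folded/unfolded) model with linear baselines. The default
#' `"symmetric"` model uses the van't Hoff exponent linearized about the
#' midpoint, so the transition is exactly symmetric in temperature and
#' its first-derivative extremum coincides with `tm`; `"vant_hoff"` uses
#' the exact 1/T exponent, whose derivative extremum sits slightly below
#' the thermodynamic midpoint (by roughly 0.3 degC at dH = -40
#' kcal/mol). Hysteresis between heating and cooling ramps is emulated
#' by generating the annealing curve with its own, lower midpoint.
#'
#' @param tm Midpoint temperature (degC) at which half the molecules are
#'   unfolded.
#' @param direction `"melt"` (ascending ramp) or `"anneal"` (descending).
#' @param dH Folding enthalpy in kcal/mol; negative by the exotherm
#'   convention (folding releases heat). Controls transition width.
#' @param baseline_folded,baseline_unfolded Length-2 numeric
#'   `(intercept, slope)` giving each linear baseline as a function of
#'   temperature in degC. The folded baseline should exceed the unfolded
#'   one for the hypochromic 295 nm i-motif signal.
#' @param grid Strictly monotone temperature grid (degC).
#' @param model `"symmetric"` (default) or `"vant_hoff"`.
#' @param cfg A [sim_config()].
#' @return A tibble with columns `temperature_C`, `signal`, `direction`,
#'   `replicate`.
#' @examples
#' sim_melt_curve(tm = 40.7, cfg = sim_config(seed = 1))
#' @export
sim_melt_curve <- function(tm, direction = c("melt", "anneal"), dH = -40,
                           baseline_folded = c(0.95, 0),
                           baseline_unfolded = c(0.60, 0),
                           grid = seq(4, 95, by = 0.5),
                           model = c("symmetric", "vant_hoff"),
                           cfg = sim_config()) {
  direction <- match.arg(direction)
  model <- match.arg(model)
  if (length(grid) == 0) abort("`grid` is empty")
  if (any(diff(grid) <= 0) && any(diff(grid) >= 0) && length(grid) > 1) {
    if (!(all(diff(grid) > 0) || all(diff(grid) < 0))) {
      abort("`grid` must be strictly monotone")
    }
  }
  if (dH >= 0) abort("`dH` must be negative (folding exotherm convention)")
  if (tm < min(grid) || tm > max(grid)) {
    warn("`tm` lies outside the temperature grid span; curve generated anyway")
  }
  alpha <- unfolded_fraction(grid, tm = tm, dH = dH, model = model)
  bf <- baseline_folded[1] + baseline_folded[2] * grid
  bu <- baseline_unfolded[1] + baseline_unfolded[2] * grid
  amp <- abs((baseline_folded[1] + baseline_folded[2] * tm) -
               (baseline_unfolded[1] + baseline_unfolded[2] * tm))
  clean <- (1 - alpha) * bf + alpha * bu
  ord <- if (direction == "anneal") order(grid, decreasing = TRUE) else order(grid)
  withr::with_seed(cfg$seed, {
    purrr::map_dfr(seq_len(cfg$n_replicates), function(r) {
      tibble(
        temperature_C = grid[ord],
        signal = clean[ord] + rnorm(length(grid), 0, cfg$noise_sd * amp),
        direction = direction,
        replicate = r
      )
    })
  })
}

#' Fraction of molecules unfolded at temperature T
#'
#' @param temperature_C Temperature(s) in degC.
#' @inheritParams sim_melt_curve
#' @return Numeric vector in `[0, 1]`, increasing in temperature.
#' @export
unfolded_fraction <- function(temperature_C, tm, dH = -40,
                              model = c("symmetric", "vant_hoff")) {
  model <- match.arg(model)
  tK <- temperature_C + 273.15
  tmK <- tm + 273.15
  x <- switch(model,
    # exponent linearized about Tm: exactly symmetric in T
    symmetric = (-dH / (.R_KCAL * tmK^2)) * (temperature_C - tm),
    # exact van't Hoff 1/T form (unfolded fraction -> 1 at high T)
    vant_hoff = (dH / .R_KCAL) * (1 / tK - 1 / tmK)
  )
  1 / (1 + exp(-x))
}

#' Simulate a CD pH titration at 288 nm
#'
#' Ellipticity at 288 nm versus pH from a Hill-type sigmoid: the folded
#' (i-motif) baseline is attained at low pH, the unfolded baseline at
#' high pH, and the midpoint is the transitional pH.
#'
#' @param ph_t Transitional pH (midpoint of the folded/unfolded
#'   equilibrium).
#' @param hill Hill slope (dimensionless, > 0); larger values sharpen
#'   the transition.
#' @param theta_folded,theta_unfolded Ellipticity baselines (mdeg) of the
#'   folded and unfolded forms; must differ.
#' @param grid pH grid within `[4, 9]`; default 5.0 to 8.0 in 0.25 steps.
#' @param cfg A [sim_config()].
#' @return A tibble with columns `ph`, `ellipticity_mdeg`, `replicate`.
#' @examples
#' sim_titration(ph_t = 7.1, cfg = sim_config(seed = 1, noise_sd = 0.02))
#' @export
sim_titration <- function(ph_t, hill = 1.5, theta_folded = 8,
                          theta_unfolded = 0.5,
                          grid = seq(5, 8, by = 0.25),
                          cfg = sim_config()) {
  if (length(grid) == 0) abort("`grid` is empty")
  if (any(grid < 4) || any(grid > 9)) abort("`grid` must lie within [4, 9]")
  if (theta_folded == theta_unfolded) {
    abort("degenerate amplitude: `theta_folded` equals `theta_unfolded`")
  }
  amp <- abs(theta_folded - theta_unfolded)
  clean <- theta_unfolded +
    (theta_folded - theta_unfolded) / (1 + 10^(hill * (grid - ph_t)))
  withr::with_seed(cfg$seed, {
    purrr::map_dfr(seq_len(cfg$n_replicates), function(r) {
      tibble(
        ph = grid,
        ellipticity_mdeg = clean + rnorm(length(grid), 0, cfg$noise_sd * amp),
        replicate = r
      )
    })
  })
}

#' Simulate a deconvoluted neutral-mass peak list
#'
#' Draws `n_molecules` molecules each carrying Binomial(`n_cytosines`,
#' `p_convert`) dC-to-dU conversions, producing a mass ladder of species
#' at `ref_mass + k * delta_m`. Optionally adds sub-reference-mass
#' fragment peaks accounting for a fixed share of total abundance, as
#' chromatographic breakdown products would.
#'
#' @param ref_mass Reference neutral mass (Da) of the unconverted oligo.
#' @param n_cytosines Number of convertible cytosines per molecule.
#' @param p_convert Per-cytosine conversion probability in `[0, 1]`.
#' @param n_molecules Number of molecules sampled.
#' @param fragment_fraction Proportion of total abundance carried by
#'   fragment peaks below the reference mass; must be in `[0, 1)`.
#' @param delta_m Mass increment per dC-to-dU conversion (Da).
#' @param cfg A [sim_config()].
#' @return A tibble with columns `mass_da`, `abundance`.
#' @examples
#' sim_peak_list(ref_mass = oligo_mass(strrep("TCCC", 9)), n_cytosines = 27,
#'               p_convert = 0.33, cfg = sim_config(seed = 11))
#' @export
sim_peak_list <- function(ref_mass, n_cytosines = 27, p_convert,
                          n_molecules = 5000, fragment_fraction = 0,
                          delta_m = 0.984, cfg = sim_config()) {
  if (p_convert < 0 || p_convert > 1) abort("`p_convert` must be in [0, 1]")
  if (n_cytosines < 1) abort("`n_cytosines` must be >= 1")
  if (fragment_fraction < 0 || fragment_fraction >= 1) {
    abort("`fragment_fraction` must be in [0, 1)")
  }
  withr::with_seed(cfg$seed, {
    k <- rbinom(n_molecules, n_cytosines, p_convert)
    counts <- tabulate(k + 1L, nbins = n_cytosines + 1L)
    full <- tibble(
      mass_da = ref_mass + (0:n_cytosines) * delta_m,
      abundance = as.numeric(counts)
    ) |>
      filter(.data$abundance > 0)
    if (fragment_fraction > 0) {
      n_frag <- 5L
      w <- runif(n_frag)
      frag_total <- fragment_fraction / (1 - fragment_fraction) *
        sum(full$abundance)
      frag <- tibble(
        mass_da = sort(runif(n_frag, 0.3, 0.85)) * ref_mass,
        abundance = frag_total * w / sum(w)
      )
      full <- bind_rows(frag, full)
    }
    arrange(full, .data$mass_da)
  })
}

#' Simulate a genome with planted tandem repeats
#'
#' Builds a uniform-random A/C/G/T background and overwrites it with the
#' requested repeat elements at exact positions. The planting record is
#' attached as the `"planted"` attribute so scans can be checked against
#' ground truth.
#'
#' @param length Sequence length in bp.
#' @param planted A data frame with columns `position` (0-based start),
#'   `unit` (e.g. `"TCCC"` or `"GGGA"`) and `n` (copy count). Elements
#'   must not overlap.
#' @param cfg A [sim_config()].
#' @return A single character string with attribute `planted` (tibble).
#' @examples
#' g <- sim_genome(2000, tibble::tibble(position = 1000, unit = "TCCC", n = 9),
#'                 cfg = sim_config(seed = 5))
#' attr(g, "planted")
#' @export
sim_genome <- function(length, planted = NULL, cfg = sim_config()) {
  if (length < 1) abort("`length` must be positive")
  planted <- if (is.null(planted)) {
    tibble(position = integer(), unit = character(), n = integer())
  } else {
    as_tibble(planted)
  }
  if (nrow(planted) > 0) {
    planted <- arrange(planted, .data$position)
    starts <- planted$position
    ends <- starts + nchar(planted$unit) * planted$n
    if (any(ends > length) || any(starts < 0)) {
      abort("planted element extends outside the sequence")
    }
    if (nrow(planted) > 1 && any(starts[-1] < ends[-nrow(planted)])) {
      abort("planted elements overlap")
    }
  }
  seq <- withr::with_seed(cfg$seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  })
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(planted))) {
    ins <- strsplit(strrep(planted$unit[i], planted$n[i]), "", fixed = TRUE)[[1]]
    chars[(planted$position[i] + 1):(planted$position[i] + length(ins))] <- ins
  }
  structure(paste(chars, collapse = ""), planted = planted)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences (names become
#'   FASTA headers), or a clone tibble with `clone_id` and `sequence`
#'   columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$clone_id)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
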