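#' Run the full synthetic reproduction workflow
#'
#' Composes every stage of the package over seeded synthetic fixtures
#' that mirror the published study conditions, and returns (optionally
#' writes as JSON) a single summary:
#'
#' * suppression model: the probability that an unsuppressed i-motif
#'   (per-cycle escape probability 0.05) impairs replication at least
#'   once in 25 cycles;
#' * transitional pH recovery: 3-replicate 13-point CD titrations
#'   (pH 5-8, 0.25 steps, 2% amplitude noise) generated at the reference
#'   pH_T values for d(TCCC)5 (6.7) and d(TCCC)9 (7.1), then re-fitted;
#' * Tm recovery: noise-free two-state melting curves (4-95 degC, 1 degC
#'   steps, dH = -40 kcal/mol, flat baselines) at the d(TCCC)9 midpoints
#'   for buffer pH 6.5 (40.7) and pH 5.3 (66.7), plus an annealing ramp
#'   at the published Ta to demonstrate hysteresis;
#' * bisulfite conversion: 500 clones of a 200 bp region holding one
#'   (TCCC)9 element, element cytosines converted at the published
#'   genomic rate (37.4%), re-called after bisulfite-mode alignment;
#' * deletion calling: a 27-clone fixture with 5 planted 8 bp deletions
#'   12 bp 5' of a (TCCC)5 element (expected 18.5%), and a 27-clone
#'   fixture in which every clone carries a deletion overlapping the 5'
#'   boundary of a (TCCC)9 element (expected 100%);
#' * mass distribution: a 5000-molecule binomial(27, 0.33) peak list
#'   assigned on the 0.984 Da ladder (expected modal k = 9), and a
#'   variant with 8% fragment abundance (expected intact fraction 92%);
#' * repeat scan: a 10 kb synthetic genome with planted elements,
#'   rescanned;
#' * the stability-versus-deletion profile association on the bundled
#'   length profile.
#'
#' Per-stage seeds are derived deterministically from `seed`, so the
#' whole bundle is reproducible from one integer.
#'
#' @param seed Base integer seed.
#' @param out Optional path; when given the summary is written there as
#'   JSON.
#' @param verbose Print stage progress to stderr.
#' @return A named list (invisibly when `out` is given).
#' @examples
#' \donttest{
#' res <- run_workflow(seed = 1)
#' res$suppression
#' }
#' @export
run_workflow <- function(seed = 1, out = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[run_workflow] ", ...)

  say("suppression model")
  suppression <- tibble(
    p_unsuppressed = 0.05, cycles = 25,
    impairment_probability = impairment_probability(0.05, 25)
  )

  say("CD titration recovery")
  titration <- purrr::map2_dfr(
    c("d(TCCC)5", "d(TCCC)9"), c(6.7, 7.1),
    function(label, true_ph_t) {
      cfg <- sim_config(seed = derive_seed(seed, if (true_ph_t > 7) 2 else 3),
                        noise_sd = 0.02, n_replicates = 3)
      fit <- fit_titration(sim_titration(ph_t = true_ph_t, hill = 1.5,
                                         cfg = cfg))
      tibble(label = label, true_ph_t = true_ph_t,
             fitted_ph_t = fit$ph_t, ph_t_se = fit$ph_t_se,
             n_points = fit$n)
    }
  )

  say("UV melting recovery")
  grid <- seq(4, 95, by = 1)
  melting <- purrr::pmap_dfr(
    list(c("d(TCCC)9 pH 6.5", "d(TCCC)9 pH 5.3"), c(40.7, 66.7)),
    function(label, true_tm) {
      curve <- sim_melt_curve(tm = true_tm, grid = grid, dH = -40,
                              cfg = sim_config(seed = derive_seed(seed, 4)))
      tibble(label = label, true_tm = true_tm,
             estimated_tm = first_derivative_midpoint(curve, window = 5),
             n_points = length(grid))
    }
  )
  hyst_curves <- bind_rows(
    sim_melt_curve(tm = 40.7, direction = "melt", grid = grid,
                   cfg = sim_config(derive_seed(seed, 5), 0.005, 3)),
    sim_melt_curve(tm = 30.3, direction = "anneal", grid = grid,
                   cfg = sim_config(derive_seed(seed, 6), 0.005, 3))
  )
  hysteresis <- melt_stats(hyst_curves)

  say("bisulfite conversion (500 clones)")
  ref9 <- .workflow_reference(n_unit = 9, total_len = 200,
                              seed = derive_seed(seed, 7))
  el9 <- filter(ref9$elements, .data$n == 9)
  clones9 <- sim_clone_set(
    ref9, n_clones = 500, rates = bisulfite_rates(p_cc_plus = 0.374),
    cfg = sim_config(seed = derive_seed(seed, 8))
  )
  alns9 <- align_clones(ref9, clones9)
  conversion <- call_conversions(alns9, el9, scope = "element")

  say("deletion calling fixtures")
  del_low <- .workflow_deletion_fixture(seed, n_unit = 5, carriers = 1:5,
                                        offset = -12L, len = 8L, k = 9)
  del_full <- .workflow_deletion_fixture(seed, n_unit = 9, carriers = 1:27,
                                         offset = -6L, len = 12L, k = 10)
  deletions <- tibble(
    fixture = c("5 of 27 upstream", "27 of 27 overlap 5'"),
    n_clones = 27,
    deletion_frequency = c(attr(del_low, "deletion_frequency"),
                           attr(del_full, "deletion_frequency"))
  )

  say("mass distribution")
  ref_mass <- oligo_mass(strrep("TCCC", 9))
  pk <- sim_peak_list(ref_mass, 27, p_convert = 0.33, n_molecules = 5000,
                      cfg = sim_config(seed = derive_seed(seed, 11)))
  mass_stats <- distribution_stats(assign_du_counts(pk, ref_mass))
  pk_frag <- sim_peak_list(ref_mass, 27, p_convert = 0.33,
                           n_molecules = 5000, fragment_fraction = 0.08,
                           cfg = sim_config(seed = derive_seed(seed, 12)))
  intact <- distribution_stats(assign_du_counts(pk_frag, ref_mass))

  say("repeat scan on synthetic genome")
  planted <- tibble(position = c(1000L, 4000L, 8000L),
                    unit = c("TCCC", "GGGA", "TCCC"),
                    n = c(9L, 6L, 5L))
  genome <- sim_genome(10000, planted, cfg = sim_config(derive_seed(seed, 13)))
  found <- find_repeat_elements(genome, min_n = 5)
  scan <- tibble(n_planted = sum(planted$n >= 5), n_found = nrow(found))

  say("length profile association")
  profile <- profile_association(tccc_length_profile(), ph_threshold = 7.0)

  summary <- list(
    seed = seed,
    suppression = suppression,
    titration = titration,
    melting = melting,
    hysteresis = hysteresis,
    conversion = conversion,
    deletions = deletions,
    mass = bind_rows(
      mutate(mass_stats, fixture = "no fragments", n_molecules = 5000),
      mutate(intact, fixture = "8% fragments", n_molecules = 5000)
    ),
    scan = scan,
    profile = profile
  )
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(summary))
  }
  summary
}

# 200 bp reference with one centered (TCCC)k element on random flanks;
# the element annotation comes from the planting record, not a rescan, so
# a chance flank extension of the repeat cannot change the element table
.workflow_reference <- function(n_unit, total_len = 200, seed = 1) {
  el_len <- 4L * n_unit
  pos <- as.integer((total_len - el_len) %/% 2)
  id <- paste0("synthetic_TCCC", n_unit)
  g <- sim_genome(total_len,
                  tibble(position = pos, unit = "TCCC", n = n_unit),
                  cfg = sim_config(seed = seed))
  elements <- tibble(
    seq_id = id, start = pos, end = pos + el_len, n = n_unit,
    unit = "TCCC", c_rich_strand = "+",
    g4_competent = n_unit > 3, imotif_neutral_ph = n_unit >= 7,
    imotif_pht_above7 = n_unit >= 9
  )
  reference_region(as.character(g), id = id, elements = elements)
}

# deletion fixture: 27 clones, planted deletion of `len` bp starting at
# element start + offset in the given carrier clones
.workflow_deletion_fixture <- function(seed, n_unit, carriers, offset, len,
                                       k) {
  ref <- .workflow_reference(n_unit = n_unit, seed = derive_seed(seed, 20 + k))
  el <- filter(ref$elements, .data$n == n_unit)
  dstart <- el$start[1] + offset
  dels <- tibble(clone = carriers, start = dstart, end = dstart + len)
  clones <- sim_clone_set(ref, n_clones = 27, deletions = dels,
                          cfg = sim_config(seed = derive_seed(seed, 30 + k)))
  alns <- align_clones(ref, clones)
  call_deletions(alns, el, window = 50, min_del_len = 2)
}
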