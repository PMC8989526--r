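# imotifkit

Tools for linking the length of d(TCCC)n tandem repeats to i-motif
stability in vitro and to spontaneous 5'-oriented deletions in genomic
DNA.

C-rich repeats fold into i-motifs — four-stranded structures of
intercalated, hemiprotonated C:C+ base pairs — preferentially at acidic
pH, but long enough tracts fold near neutral pH. An i-motif formed on
genomic DNA displaces the repeat from the duplex, leaves its cytosines
accessible to bisulfite, and marks a site where replication can stall and
delete sequence 5' of the repeat on the C-rich strand. `imotifkit`
implements the full analysis chain for this phenomenon:

* **Repeat scanning** (`find_repeat_elements()`, `annotate_c_runs()`,
  `scan_fasta()`): strand-aware maximal whole-unit runs of d(TCCC)n /
  d(GGGA)n with competence flags (G-quadruplex at n > 3, i-motif at
  neutral pH at n ≥ 7, transitional pH above 7 at n ≥ 9) and the
  (4n − 1) oligo-dC rule; BED6 output.
* **UV melting** (`first_derivative_midpoint()`, `melt_stats()`,
  `compute_tds()`): the first-derivative method with local-quadratic
  smoothing and parabolic refinement; Tm, Ta, hysteresis over replicate
  ramps; normalized thermal difference spectra (max = +1).
* **CD pH titrations** (`fit_titration()`, `fraction_folded()`,
  `classify_cd_spectrum()`): four-parameter Hill sigmoid
  θ(pH) = θᵤ + (θ_f − θᵤ)/(1 + 10^{n_H(pH − pH_T)}) fitted by
  Levenberg–Marquardt; pH_T with its standard error from the fit
  covariance; band-rule classification of spectra.
* **Bisulfite clone analysis** (`align_clones()`, `call_conversions()`,
  `call_deletions()`, `region_report()`): global affine-gap alignment in
  which (reference C, read T) scores as a match; per-element C→T
  conversion frequencies; deletion events classified against the element
  (UPSTREAM_5P / OVERLAP_5P / INTERNAL / OVERLAP_3P / DOWNSTREAM_3P /
  OUTSIDE) and the fraction of clones with a 5'-associated deletion.
* **Mass-shift analysis** (`oligo_mass()`, `assign_du_counts()`,
  `distribution_stats()`): average oligo masses, assignment of
  deconvoluted neutral-mass peaks to the +0.984 Da dC→dU ladder, and the
  conversion-count distribution (mode, mean, intact fraction).
* **Deletion model** (`impairment_probability()`,
  `profile_association()`): the suppression-failure probability
  1 − (1 − p)^cycles, and the rank association between in-vitro pH_T and
  per-locus deletion fraction with a pH-threshold consistency check.
* **Synthetic data** (`sim_melt_curve()`, `sim_titration()`,
  `sim_clone_set()`, `sim_peak_list()`, `sim_genome()`): seeded,
  reproducible generators for every input type, so the entire pipeline is
  testable without instrument data.

Results are tibbles (or small S3 objects with `tidy()` / `glance()` /
`augment()` / `autoplot()` methods), so everything composes with the
pipe.

## A worked example

Simulate a 3-replicate CD titration of the 9-repeat at 2% noise, refit
it, and ask how folded the sequence would be at the bisulfite reaction pH:

```r
library(imotifkit)

ser <- sim_titration(ph_t = 7.1, hill = 1.5, cfg = sim_config(1, 0.02, 3))
fit <- fit_titration(ser)
fit
#> <titration_fit>
#>   pH_T        7.091 +/- 0.012
#>   Hill slope  1.601
#>   baselines   folded 7.98 / unfolded 0.63 mdeg
#>   rss 0.6204 over 39 points
round(fraction_folded(fit, 5.3), 4)
#> [1] 0.9986
```

The fitted transitional pH (7.09 ± 0.01) recovers the generating value
7.1, and at pH 5.3 — the bisulfite reaction condition — essentially the
whole population is i-motif. Melting ramps work the same way:

```r
curves <- dplyr::bind_rows(
  sim_melt_curve(tm = 40.7, direction = "melt",   grid = seq(4, 95, 1),
                 cfg = sim_config(1, 0.005, 3)),
  sim_melt_curve(tm = 30.3, direction = "anneal", grid = seq(4, 95, 1),
                 cfg = sim_config(2, 0.005, 3))
)
melt_stats(curves)
#> # A tibble: 1 × 7
#>   tm_mean tm_sd ta_mean ta_sd hysteresis n_melt n_anneal
#>     <dbl> <dbl>   <dbl> <dbl>      <dbl>  <int>    <int>
#> 1    40.6  1.98    29.6  1.07       11.0      3        3
```

Tm ≈ 40.7 °C with ~11 °C of hysteresis — the signature of slow i-motif
folding. Scanning and the suppression model:

```r
find_repeat_elements(paste0("AA", strrep("TCCC", 9), "GG"))
#> # A tibble: 1 × 9
#>   seq_id start   end     n unit  c_rich_strand g4_competent imotif_neutral_ph
#> 1 seq        2    38     9 TCCC  +             TRUE         TRUE
#> # imotif_pht_above7 TRUE

impairment_probability(0.05, 25)
#> [1] 0.7226104
```

A repeat whose i-motif escapes suppression 5% of the time per replication
cycle has a 72% chance of impairing replication at least once in 25
cycles. `run_workflow(seed = 1)` chains every stage — scan, melt,
titrate, bisulfite conversion and deletion calling, mass distribution,
profile association — over seeded fixtures and returns one summary list
(optionally written as JSON).

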