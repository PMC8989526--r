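---
title: "Linking d(TCCC)n repeat length, i-motif stability and 5'-oriented deletions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking d(TCCC)n repeat length, i-motif stability and 5'-oriented deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imotifkit)
library(dplyr)
```

## The scientific question

C-rich tandem repeats d(TCCC)n can fold into i-motifs: four-stranded
structures built from intercalated, hemiprotonated C:C+ base pairs. Because
the pairing requires N3 protonation of cytosine, folding is favoured at
acidic pH, but sufficiently long tracts fold near neutral pH too. The
complementary G-rich strand folds into G-quadruplexes over a much wider
length range. An i-motif that forms on genomic DNA displaces the repeat
from the duplex, leaving its cytosines chemically accessible and creating a
structure that can stall replication. This package ties together five
measurements of that chain of events:

1. **Repeat scanning** — where d(TCCC)n / d(GGGA)n elements sit in a
   sequence, with length-dependent competence flags.
2. **UV melting** — thermal stability (Tm), annealing midpoints (Ta) and
   their hysteresis, plus thermal difference spectra (TDS).
3. **CD pH titration** — the transitional pH (pH~T~), the pH at which half
   the molecules are folded.
4. **Bisulfite probing of native DNA** — cloned PCR products aligned to the
   reference; C→T conversions report single-stranded/i-motif cytosines and
   gap runs report deletions, which cluster 5' of the repeat on the C-rich
   strand. A parallel mass-spectrometric readout counts dC→dU conversions
   per molecule through +0.984 Da mass shifts.
5. **A suppression-failure model** — the probability that an i-motif that
   escapes repair-mediated suppression with per-cycle probability *p*
   impairs replication at least once in *c* cycles,
   `1 - (1 - p)^c`.

Since no raw instrument or sequencing data are distributed with the study,
the package ships seeded generators for every input type; all tests and the
acceptance script run on synthetic data whose parameters are the study
conditions.

## Models and estimators

### Two-state melting and the first-derivative Tm

`sim_melt_curve()` emulates an A~295~ ramp as a two-state equilibrium with
linear baselines:

$$A(T) = (1-\alpha)\,b_f(T) + \alpha\,b_u(T)$$

The default `model = "symmetric"` writes the unfolded fraction as a
logistic in temperature with slope set by the van't Hoff enthalpy at the
midpoint, $\alpha = 1/(1+\exp[(\Delta H/ R T_m^2)(T - T_m)])$ (with
$\Delta H < 0$ by the folding-exotherm convention). This form is exactly
symmetric about T~m~, so the first-derivative estimator has zero model
bias and its exactness can be tested to 0.1 °C. The exact 1/T exponent is
available as `model = "vant_hoff"`; its derivative extremum sits slightly
below the thermodynamic midpoint (about 0.3 °C at ΔH = −40 kcal/mol,
more for broader transitions), a distinction that matters only for
synthetic benchmarking, not for real ramps whose noise dominates.
Hysteresis between heating and cooling is emulated by giving the annealing
ramp its own, lower midpoint, matching how slow i-motif folding kinetics
manifest in practice.

`first_derivative_midpoint()` implements the classic first-derivative
method: local-quadratic smoothing (default window 5 points; unsmoothed
differences are noise-dominated), central differences on the possibly
uneven grid, the global extremum of |dA/dT|, and parabolic interpolation
through the extremum triple to refine below grid resolution. The absolute
derivative is used because the 295 nm i-motif signal is hypochromic
(negative slope on melting) while other wavelengths can give positive
slopes. A flat curve returns an explicit `NA` ("no transition") rather
than an arbitrary temperature. Duplicate-temperature points — instrument
hold segments — are dropped first. `melt_stats()` analyses each replicate
ramp independently and averages the midpoints (the per-replicate analysis
is also how triplicates are treated in the reference tables), reporting
`hysteresis = tm_mean - ta_mean` by default with a paired per-replicate
mode as an alternative; the bundled `tccc_melt_table()` keeps the
published values verbatim, and `melt_table_consistency()` shows that the
printed hysteresis agrees with Tm − Ta within 0.15 °C everywhere except
the n = 15 row (1.0 °C off; kept verbatim, flagged).

### The titration sigmoid and pH~T~

`fit_titration()` fits ellipticity at 288 nm versus pH to a four-parameter
Hill-type sigmoid

$$\theta(\mathrm{pH}) = \theta_u + \frac{\theta_f - \theta_u}
  {1 + 10^{\,n_H(\mathrm{pH} - \mathrm{pH}_T)}}$$

by Levenberg–Marquardt least squares. The reference analysis states only
that pH~T~ is "the inflection point of fitted ellipticity"; the Hill form
with a free slope is this package's choice, with the slope bounded to
(0.2, 10] so that a noise spike cannot be fitted as a step. Starting
values are data-driven (baselines from the 10% extreme-pH quantiles,
midpoint from the half-amplitude crossing, slope 1), and the pH~T~
standard error comes from the fit covariance — the same convention as the
published "± 0.01–0.08" values. `fraction_folded()` inverts the fit:
exactly 0.5 at pH~T~, monotone in pH. A fit whose midpoint falls outside
the sampled span is flagged as extrapolated rather than silently reported.
`classify_cd_spectrum()` applies the textbook band rules (positive
285–292 nm with negative 255–270 nm → i-motif; positive 260–268 nm with
negative 235–245 nm → parallel G-quadruplex) to a lightly smoothed scan.

### Repeat scanning

`find_repeat_elements()` reports maximal whole-unit tandem runs of the
4-mer unit on both strands, with the C-rich strand as the canonical
reporting frame (deletion orientation is defined on that strand). Only
integral copy counts are used — a trailing partial unit does not extend a
run — and `N` breaks a run. Flags encode the length thresholds: G4
competence at n > 3, i-motif folding at neutral pH at n ≥ 7, pH~T~ above 7
at n ≥ 9. `annotate_c_runs()` applies the empirical (4n − 1) rule for
oligo-dC tracts (m ≥ 11 and m ≡ 3 mod 4). Because TCCC is not
self-overlapping, maximal runs are unique and no phase tie-breaking is
needed. `scan_fasta()` emits deterministic BED6.

### Bisulfite clone analysis

`align_clones()` wraps global Needleman–Wunsch alignment with affine gaps
(match +1, mismatch −2, gap open 5, gap extend 1, end gaps penalized since
clones are full-length PCR products). In bisulfite mode the asymmetric
cell (reference C, read T) scores as a full match, so chemical conversions
are never pushed into gaps; a consequence worth knowing is that gap
placements that differ only by C↔T interchange are exactly equally scored,
so a deletion through a converted tract can be reported at any equivalent
offset (side classification is robust to this). Each clone is
orientation-checked by also aligning its reverse complement and keeping
the better score. `call_conversions()` counts (C,T) columns over (C,T)
plus (C,C), excluding gapped or A/G read bases from the denominator;
`call_deletions()` turns maximal read-gap runs of at least 2 bp (1 bp gaps
are ambiguous with cloning artifacts) into events classified against the
element interval, with a 50 bp flank window — no precise distance defines
what counts as near the 5' end, so the window is configurable, and moving
it only exchanges events between flank classes and OUTSIDE. The
deletion frequency counts clones with at least one 5'-associated event
(upstream, 5'-overlapping or internal). Because the reported per-read mean
conversion count can be computed over the element or the whole region —
and the published 10.8/36mer figure sits between the two — the region
report emits both.

### Mass-shift analysis

`oligo_mass()` uses average residue masses (ESI deconvolution of 36mers
reports average neutral masses); the d(TCCC)~9~ 36mer computes to
10483.70 Da with the 5'-OH convention. Each dC→dU conversion adds
0.984 Da (the nominal "1 Da"); `assign_du_counts()` snaps peaks to the
`ref + k·0.984` ladder within a 0.35 Da tolerance (below half the ladder
spacing, so assignment is unambiguous) and reports abundance-weighted
frequencies, with sub-reference-mass abundance feeding the intact-fraction
complement. `distribution_stats()` gives the mode (ties to the smaller k),
the abundance-weighted mean and the intact fraction.

### The deletion model

`impairment_probability(p, cycles)` is evaluated in log space
(`-expm1(cycles * log1p(-p))`); at p = 0.05 and 25 cycles it returns
0.7226, printed as 0.72. `profile_association()` summarizes the bundled
locus table (`tccc_length_profile()`): a Spearman rank correlation between
pH~T~ and deletion fraction — the published analysis plots but never tests
this association, so a descriptive rank statistic for a five-locus
monotone claim is deliberate, with no p-value headline — plus the
threshold consistency check that every locus with pH~T~ > 7 deleted in
100% of clones. A constant column yields an explicit undefined sentinel,
never a silent 0. Loci lacking a printed value (BCR's denominator, the
n = 11 entry absent from the stability table) are stored as NA/counts and
dropped from the statistics with a message.

## What the generators emulate — and what they do not

* Melting curves: two-state transitions, linear baselines, Gaussian noise
  proportional to amplitude, direction-specific midpoints for hysteresis.
  Not emulated: kinetic (scan-rate-dependent) curve shapes, baseline
  drift, multi-state intermediates.
* Titrations: the same sigmoid family the fitter assumes, which makes the
  recovery tests self-consistency checks — they demonstrate estimator
  correctness, not robustness to model misspecification.
* Clone sets: independent per-cytosine conversion with state-dependent
  rates (defaults 0.45/0.35/0.05/0.01 for protonated single-stranded,
  C:C+ paired, single-stranded, and duplex cytosines — ordered by the
  frontier-orbital reactivity ranking, scaled so an i-motif element
  converts at roughly the level observed for d(TCCC)9 in native DNA) and
  exact planted deletions. Not emulated: sequencing error, PCR chimeras,
  strand-resolution artifacts.
* Peak lists: binomial conversion counts over 27 cytosines with optional
  fragment abundance below the reference mass. Not emulated: isotope
  envelopes, adducts, deconvolution artifacts.
* Genomes: uniform random background with exactly planted repeats — no
  base composition or repeat-family realism, which is why the genome-wide
  site count is reported per supplied FASTA without claiming to match any
  particular assembly's tally.

Passing tests on these fixtures therefore validate the estimators and the
bookkeeping (coordinates, classes, frequencies) under the stated noise
models; they cannot certify behaviour on instrument quirks the generators
do not model.

## Numerical choices and problem sizes

Seeds are explicit everywhere (`sim_config()`), consumed via isolated RNG
scopes, with per-stage streams derived arithmetically from one base seed
in `run_workflow()`. Default problem sizes keep every check comfortably
within desk scale: 92-point melting grids, 13-point titration grids with
three replicates, 500 clones for conversion recovery (binomial SE ≈ 0.4
percentage points on 13 500 cytosine draws), 27-clone deletion fixtures
matching the published clone tallies, 5000-molecule peak lists. The
oracle-agreement suites use dozens to hundreds of random sequences per
run. Degenerate inputs fail loudly: empty grids, flat curves, degenerate
TDS differences, zero conversion denominators and all-unassigned peak
lists are errors or explicit NA results, never silent zeros.

## A worked pass through the whole pipeline

```{r workflow, eval = FALSE}
res <- run_workflow(seed = 1)
res$suppression$impairment_probability  # 0.7226
res$titration                            # fitted pH_T 6.70 / 7.10
res$melting                              # estimated Tm 40.7 / 66.7
res$deletions$deletion_frequency         # 0.185, 1.00
res$mass$mode_k                          # 9
```

`run_workflow()` also writes the bundle as JSON when given `out =`, and
`scripts/acceptance.R` recomputes the same quantities from scratch for any
seed.

## Known limitations

* The titration recovery tests share the sigmoid family between generator
  and fitter; no misspecification stress is included.
* The bisulfite aligner resolves gap placement deterministically but, as
  noted, placements equivalent under C→T interchange are arbitrary within
  their equivalence class.
* The modal dU count at the published 0.33 conversion rate sits on a
  near-tie between k = 8 and k = 9 (probability ratio 1.04), so
  single-draw modes at 5000 molecules occasionally report 8; the
  distribution summary follows the published practice of averaging
  replicate input levels.
* `profile_association()` is descriptive; with five loci (three complete)
  a rank correlation has no useful sampling distribution and none is
  reported.
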