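Package: imotifkit
Title: i-Motif Repeat Stability and Deletion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Links the length of d(TCCC)n tandem repeats to i-motif
    stability in vitro and to spontaneous 5'-oriented deletions in
    genomic DNA. Provides strand-aware tandem-repeat scanning with
    structure-competence annotation, first-derivative melting analysis
    (Tm, Ta, hysteresis) and thermal difference spectra from UV ramps,
    sigmoid fitting of CD pH titrations for the transitional pH (pHT),
    global alignment of bisulfite-converted clones with C-to-T
    conversion and deletion-event calling, mass-ladder assignment of
    dC-to-dU conversion counts from deconvoluted ESI spectra, a
    replication-cycle suppression-failure probability model, and seeded
    synthetic-data generators for every input type so the full analysis
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
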