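Package: neoms
Title: Microstate Analysis of Neonatal EEG Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for EEG microstate analysis of preterm neonatal
    recordings: preprocessing (zero-phase Butterworth bandpass, rational
    resampling, common-average re-referencing), polarity-invariant modified
    k-means microstate segmentation with Krzanowski-Lai selection of the
    number of maps, backfitting with temporal smoothing, microstate metrics
    (duration, occurrence, coverage, global explained variance), syntax
    statistics (observed versus expected transition probabilities, randomized
    chi-square test), topographic permutation tests (TANOVA), Hurst exponents
    of microstate sequences via detrended fluctuation analysis, and a
    synthetic preterm cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
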