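Package: msrehab
Title: EEG Microstate and EMG Analysis for Stroke Rehabilitation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synchronized resting-state EEG and surface EMG
    recordings from motor-rehabilitation studies. Implements the EEG microstate
    pipeline (global field power, GFP-peak extraction, polarity-invariant
    modified K-means topographic clustering, group-template aggregation,
    competitive backfitting, and duration/coverage/occurrence statistics),
    time-domain EMG features (peak-to-peak and root-mean-square amplitude),
    and the accompanying statistical layer (paired and independent comparisons,
    exact Wilcoxon signed-rank, mixed two-way ANOVA with partial eta squared
    and simple effects, Bonferroni and Benjamini-Hochberg correction, and
    change-score correlation matrices). A seeded semi-Markov simulator
    generates EEG with planted microstate sequences and EMG with known
    analytic features so the whole pipeline is testable without access
    to clinical recordings; the clinical outcome table of a 20-patient
    rTMS cohort ships as a plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
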