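Package: oysterClock
Title: Chronobiological Rhythm Validation and Clock-Gene Expression Analysis for Bivalve Valve-Activity Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating behavioral rhythms in bivalve valve-activity
    time series and for the molecular analyses that accompany them. Implements
    the full chronobiological validation chain used in oyster valvometry
    studies: autocorrelation-based quality control, Lomb-Scargle spectral
    analysis with false-alarm thresholds, Cosinor rhythmometry (amplitude,
    acrophase, mesor, percent rhythm) with zero-amplitude and elliptic
    validation tests, Halberg-style period confidence intervals, detection of
    secondary periodicities by residual reinjection, period classification
    (ultradian/circadian/infradian), population summaries and double-plotted
    actograms. Also provides comparative-Ct (2^-ddCt) relative quantification
    of qPCR data, reference-gene stability screening, per-timepoint ANOVA /
    Kruskal-Wallis comparisons with Holm-Sidak adjustment, Spearman
    co-expression matrices and correlation-based gene grouping, plus sequence
    utilities (longest-ORF accounting, translation, E-box promoter scanning).
    Synthetic-data generators emulating the laboratory designs make every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    car,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
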