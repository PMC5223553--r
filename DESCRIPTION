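Package: mdinet
Title: Mass Difference Network Analysis for Direct-Infusion FT-ICR-MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for ultrahigh-resolution direct-infusion mass
    spectrometry metabolomics built around exact-mass molecular formula
    annotation. Provides peak-list ingestion with signal-to-noise filtering,
    linear recalibration against a reference mass list, ppm-window alignment
    of samples into a feature matrix, replicate-presence filtering and
    IQR-Euclidean normalization; combinatorial molecular formula assignment
    over a configurable element grid with Senior-rule, elemental-ratio and
    13C-isotopologue validation, plus network-based propagation of formulas
    to low-abundance peaks; mass difference networks (MDiN) built from
    reaction-equivalent mass differences and mass difference enrichment
    analysis (MDEA) via Fisher's exact test; Z-scaling, PCA with group tests
    on component scores, and loading correlation between datasets. Also
    includes a Poisson single-hit limiting-dilution frequency estimator for
    viral reactivation assays, 2^-dCt relative expression helpers, and a
    ground-truthed synthetic metabolome generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
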