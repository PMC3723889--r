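Package: epimsap
Title: Methylation-Sensitive AFLP Scoring and Transgenerational
    Epigenetic Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dominant-marker population epigenetics based on
    methylation-sensitive amplified polymorphism (MSAP) assays run with the
    isoschizomers HpaII and MspI. Converts paired presence/absence band
    matrices into quality-filtered methylation-state matrices (replicate-based
    error estimation, size and error-rate filtering, methylation-susceptible
    locus classification, three-condition scoring), quantifies epigenetic
    differentiation among populations (per-locus Fisher exact tests with
    Storey q-values, one-level AMOVA with permutation-tested Phi-st, pairwise
    Phi-st, nonmetric multidimensional scaling, Mantel tests, polymorphism
    summaries), and analyses the persistence of methylation marks through
    male gametogenesis in paired sporophyte-gametophyte designs (change
    tables with ambiguity resolution, per-locus instability with exact
    binomial intervals, Hartigan dip test of unimodality, stable/unstable
    mixture classification, binomial GLMs of change probability). A fully
    parameterised synthetic-data generator with known ground truth supports
    calibration and end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    MASS,
    Rcpp,
    emmeans,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    vegan,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
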