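Package: roseonet
Title: Guild Screening, Trait Placement, Seasonality and Co-Occurrence
    Networks for Marine Amplicon Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking a reference-defined bacterial guild (the
    marine Roseobacter group) to phylogenetically inferred
    DMSP-producing phytoplankton in 16S/18S rRNA amplicon time series.
    Provides reference-based sequence identity screening of 16S ASVs,
    maximum-likelihood phylogenetic placement of 18S ASVs onto a
    trait-labelled reference tree with producer-class grading,
    Bray-Curtis time-lag seasonality statistics (Mantel correlograms and
    season-interval Kruskal-Wallis tests), permutation-based community
    comparisons (ANOSIM, SIMPER), maximal/total information coefficient
    (MICe/TICe) co-occurrence network inference with null calibration,
    and a synthetic multi-site community simulator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    vegan,
    igraph,
    jsonlite,
    yaml,
    car,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
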