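Package: satkit
Title: Detection, Alignment and Family Clustering of Satellite DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for annotating long tandem repeats (satellites) in genome
    assemblies and organising them into families. Satellites are detected by
    clustering exact decamer seeds in fixed-size windows, extending arrays
    along the chromosome, segmenting them into repeat units and applying a
    repeat-length regularity filter. Repeat units are compared with a
    cyclic-permutation- and strand-aware global aligner whose normalised
    scores drive progressive clustering into families within a species and
    super-families across species, calibrated against an empirical
    random-sequence null. Additional modules score satellites against a
    CENP-A chromatin affinity track (WIG), scan genomes for perfect
    microsatellites and A/T tracts, summarise catalogs as repeat-size
    histograms and densities, and simulate genomes with planted repeats for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    generics,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
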