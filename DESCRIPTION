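Package: epihybridr
Title: Methylome Remodeling and Epigenetic QTL Mapping in F1 Epihybrid Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing DNA methylome remodeling and heterosis in
    panels of F1 epigenetic hybrids derived from crossing a recurrent
    wild-type parent to epigenetic recombinant inbred lines (epiRILs).
    Implements trio-based classification of 200-bp methylation regions into
    additive and trans-chromosomal (de)methylation scenarios, bootstrap
    enrichment of differentially methylated regions among remodeled regions,
    genome-wide co-remodeling correlation analysis, epigenetic QTL interval
    mapping by Haley-Knott regression with permutation thresholds,
    mid-parent heterosis and variance-component analysis with a conditional
    epigenome-wide association study, count normalization and region-gene
    linking, causal model selection among fixed DAG structures, and the
    analytic dominance/epistasis decomposition of QTL contrasts. A
    synthetic-data generator emulating the epiRIL pedigree and cross design
    makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    cluster,
    edgeR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
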