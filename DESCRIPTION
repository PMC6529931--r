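Package: chromwire
Title: Chromatin Landscape Callers and Enhancer Wiring for Leukemia Epigenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Callers and integration tools for multi-omics chromatin analyses
    of chronic lymphocytic leukemia against normal B cells: partially
    methylated domain (PMD) calling from whole-genome bisulfite methylomes
    with cross-sample consensus, differentially methylated region (DMR)
    calling with a B-cell-maturation filter, promoter H3K4me3 broadening and
    nucleosome-gain detection, Gaussian-mixture derived fold-change
    thresholds, bidirectional (eRNA) transcription detection from stranded
    coverage, active-enhancer consensus annotation from chromatin states,
    single-cell ATAC co-accessibility wiring with permutation-calibrated
    thresholds and rewired-promoter calling, and assembly of a gene
    regulatory enhancer network (GREN). Ships seeded synthetic-data
    generators that emulate the statistical structure of each input so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    Matrix,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
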