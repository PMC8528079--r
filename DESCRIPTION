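Package: degkit
Title: Structure-Aware Modelling of Per-Nucleotide RNA Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for modelling in-line hydrolysis of RNA from sequence
    and secondary structure. Implements windowed one-hot sequence/loop-type
    regression of per-nucleotide degradation (linear ridge and boosted-tree
    variants), multi-target MCRMSE evaluation with signal-to-noise
    accounting, clustering-based blind test-set curation, whole-mRNA
    half-life prediction by per-linkage rate summation, motif-level signal
    aggregation, genetic-algorithm model ensembling, and a seeded synthetic
    construct generator with a planted ground-truth model. Reads and writes
    the JSON-lines construct dialect used by RNA stability community
    benchmarks, FASTA, base-pair probability matrices, and prediction
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
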