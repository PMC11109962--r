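Package: notchdyn
Title: Dynamic Versus Static RBPJ Binding Site Analysis and Notch
    Responsiveness Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing Notch-responsive ("dynamic") from
    static RBPJ transcription-factor binding sites in replicated ChIP-seq
    data. Builds replicate-validated consensus peaks with Fisher-combined
    significance, classifies sites by normalized binding fold change under
    gamma-secretase inhibitor (GSI) treatment or washout, scans site
    sequences for canonical and degenerate RBPJ motifs, SP1 motifs and
    head-to-head RBPJ dimer sites, annotates sites relative to gene models,
    associates sites with genes through a basal-plus-extension regulatory
    domain model, trains and applies a random-forest predictor of Notch
    responsiveness, tests hypergeometric enrichment of deregulated genes,
    and stitches acetylation peaks into ranked enhancer clusters. A
    self-contained synthetic-data generator with planted ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
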