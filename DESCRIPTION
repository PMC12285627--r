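Package: lncforge
Title: Multi-Omics Feature Engineering and Imbalance-Aware Ensemble
    Prediction of Cancer lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a 44-feature multi-omics profile (epigenomic, genomic,
    transcriptomic, phenotype, network and mutation features) for intergenic
    long non-coding RNA genes from standard-format inputs (GTF, FASTA, BED,
    TSV), trains an imbalance-aware EasyEnsemble of gradient-boosted tree
    classifiers to score each gene's cancer potential, selects decision
    thresholds by maximum F1 or Neyman-Pearson false-positive-rate control,
    and explains predictions globally and per gene with additive Shapley-value
    attributions. Ships a seeded synthetic multi-omics generator with planted
    class effects so the entire pipeline is exercisable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    xgboost,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    e1071,
    ranger,
    class,
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
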