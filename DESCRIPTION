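Package: exopba
Title: Single-Exosome Surface Proteomics from Proximity Barcoding Assay Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for single-exosome surface
    proteomics measured by proximity barcoding assays (PBA), in which
    antibody-conjugated oligonucleotides on the same extracellular vesicle
    acquire a shared DNA exosome tag that is read out by sequencing. The
    package converts barcoded FASTQ reads into a deduplicated single-exosome
    by protein molecule-count matrix (quality filtering, tag parsing,
    mismatch-tolerant protein-tag matching, directional UMI collapse),
    aggregates per-sample expression with trimmed-mean-of-M-values (TMM)
    normalization and a normality-routed differential-expression scheme with
    Benjamini-Hochberg FDR control, discovers exosome subpopulations by
    self-organizing-map training with consensus metaclustering, quantifies
    per-sample subpopulation proportions and differential abundance, and
    evaluates markers as diagnostic classifiers via ROC curves with DeLong
    confidence intervals. A synthetic-data generator renders ground-truth
    cohorts as error-bearing barcoded reads for calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    edgeR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
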