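Package: allosterik
Title: Allosteric Communication Networks and Variant Phenotype Models for
    Bacterial Transcription Repressors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how natural amino acid
    variations alter allosteric communication and ligand response in dimeric
    GntR/FadR-family transcriptional repressors such as Escherichia coli
    DgoR. Provides elastic-network Gaussian trajectory generators with
    analytically known covariance, dynamic cross-correlation and
    essential-dynamics (PCA) analysis, correlation-weighted dynamical
    networks with community detection and exhaustively verified
    suboptimal-path enumeration, alignment-based variant-panel scanning with
    domain classification, and quantitative assay models (Hill and 1:1
    isotherm binding fits, effector-release titrations, growth-curve
    kinetics, fluorescence normalization).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    methods,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
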