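Package: gyrbench
Title: Mock-Community Benchmarking of gyrB/parE Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluation framework for gyrB-based amplicon sequencing of food
    microbiota, where degenerate gyrB primers co-amplify the parE paralog
    within Firmicutes. Builds paralog-aware marker reference databases by
    degenerate-primer in-silico PCR, simulates mock-community reads and
    matched qPCR measurements, clusters reads into OTUs with swarm-style
    single-linkage at a fixed edit distance, removes chimeras and rare OTUs,
    assigns gene-labelled taxonomy by best-hit identity, converts relative
    read counts to absolute abundances through qPCR calibration curves with
    per-species deviation statistics, and summarises alpha/beta diversity
    and Kimura 2-parameter neighbor-joining phylogenies. Bundled mock
    community presets allow the whole pipeline to be exercised and scored
    against known truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    vegan,
    Biostrings,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
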