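Package: crisprchrom
Title: Chromatin and Expression Correlates of CRISPR-Cas9 Mutagenesis
    Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene-level scoring of chromatin and expression covariates of
    CRISPR-Cas9 mutagenesis efficiency in early zebrafish-style embryos.
    Pools and clusters transcription start sites into transcriptional
    units, scores promoter accessibility from ATAC-seq peak calls, exon
    methylation from ChIP-seq peak calls, and promoter histone-mark
    intensity from microarray probes, then relates each feature (and
    stage-wise expression) to per-gene mutagenesis efficiency with
    rank-based statistics. Ships a seeded synthetic-study generator with
    a Gaussian-copula planted effect so the whole pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    IRanges,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
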