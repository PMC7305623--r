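Package: ncatsr
Title: Downstream Analysis of Nanopore Cas9-Targeted Sequencing for MGMT
    Methylation and IDH Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of nanopore Cas9-targeted
    sequencing (nCATS) panels that jointly assay MGMT promoter/exon-1/intron-1
    CpG methylation and IDH1/IDH2 hotspot mutations in glioma. Aggregates
    per-read 5mC log-likelihood-ratio calls into per-CpG methylation
    frequencies with read-depth and LLR-magnitude filters, runs read-subsampling
    limit-of-detection titrations on methylation standards, calls diploid
    single-nucleotide variants from base-count pileups with candidate-frequency
    and depth gates plus homopolymer flagging, classifies somatic versus
    germline status against a matched normal, and correlates and clusters
    per-CpG methylation against qRT-PCR relative expression. A seeded
    synthetic-data generator emulates methylation standards, the three-locus
    target panel, per-read call tables, variant pileups, and
    methylation-expression-coupled cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
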