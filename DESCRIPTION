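Package: amylocnv
Title: Coverage-Based Amylase Copy-Number Genotyping and Kinship-Aware
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete copy-number genotyping of the human amylase locus
    (AMY1, AMY2A, AMY2B) from whole-genome sequencing read depth, using a
    copy-invariant reference region and parity-conditional integer
    rounding that exploits the shared structural haplotypes of AMY1 and
    AMY2A.  Includes droplet digital PCR copy-number estimation and
    reconciliation against the sequencing calls, kinship-aware
    variance-component association and heritability estimation for
    adiposity traits, ancestry stratification via PCA with sliding-window
    analyses along the leading principal component, and a seeded
    simulation suite (coverage counts, miniature alignment fixtures,
    ddPCR droplets, pedigreed cohorts, structured genotype matrices) that
    emulates the statistical structure of a consanguineous cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
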