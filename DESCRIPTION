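Package: dnmkit
Title: De Novo Mutation Discovery, Phasing and Mosaicism Analysis in
    Three-Generation Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multigenerational de novo mutation (DNM) analysis in
    large three-generation pedigrees: candidate DNM discovery from joint
    genotype matrices with transmission-based validation, parent-of-origin
    phasing by three-generation haplotype transmission and by read tracing,
    classification of gonosomal (post-zygotic) and shared
    post-primordial-germ-cell-specification (post-PGCS) germline mosaic
    mutations, genotyping-error rate estimation (missed-heterozygote and
    false-positive rates), adjusted germline mutation-rate calculation, and
    family-aware identity-link Poisson regression of parental age effects.
    Includes a synthetic-cohort generator that emulates large multi-sibship
    pedigrees with known ground truth, so every stage of the pipeline can be
    exercised and validated without access to controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    rtracklayer,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
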