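Package: trioburden
Title: Mutability-Based Rare-Variant Enrichment Analysis for Trio Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements the statistical machinery of a trio-based exome
    study of congenital cerebrovascular malformation as a reusable, tested
    pipeline. Builds per-gene, per-functional-class de novo mutation
    probabilities from trinucleotide-context substitution rates; applies the
    study's de novo, rare-transmitted and recessive variant filter cascades
    with kinship and duplicate QC; tests cohort-level and per-gene de novo
    burden with one-sided Poisson statistics, estimates the attributable
    fraction and simulates gene-discovery saturation; computes
    pLI-stratified expectations and one-sided binomial tests for rare
    transmitted variants plus case-control Fisher burden; and performs
    covariate-adjusted indicator logistic regression for gene-set
    enrichment. A fully synthetic cohort generator with planted ground
    truth exercises every stage without access to patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
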