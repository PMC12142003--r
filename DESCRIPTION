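Package: hybridASE
Title: Allele-Specific Expression Analysis for Reciprocal Interspecies Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Haplotype-resolved expression analysis for reciprocal F1 hybrids
    of Caenorhabditis briggsae and Caenorhabditis nigoni. Assembles
    allele-level count tables from hybrid and parental RNA-seq counts,
    normalizes with trimmed-mean-of-M-values factors, tests two-group
    contrasts with a conditional negative-binomial exact test, classifies
    each ortholog pair into expression-inheritance modes (no change,
    dominant, additive, overdominant, underdominant) and regulatory modes
    (conserved, cis, trans), detects parent-of-origin imprinted genes from
    allelic fractions, and computes chromosome and gene-set enrichment
    statistics. A seeded synthetic-data generator with known per-gene truth
    supports recovery and calibration experiments, including
    mitochondria-restricted and transposable-element expression tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    fgsea,
    jsonlite,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
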