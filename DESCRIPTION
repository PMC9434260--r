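Package: combqtl
Title: QTL and eQTL Mapping of Comb Morphology with Outline Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interval mapping of quantitative traits and expression traits in
    an F8 advanced intercross between Red Junglefowl and White Leghorn
    chickens, together with the outline morphometrics needed to phenotype the
    comb, a sexual ornament. Provides elliptical Fourier analysis of closed
    comb outlines with generalized Procrustes alignment and shape PCA,
    Haley-Knott regression genome scans with covariates and permutation
    thresholds, 1.8-LOD-drop support intervals, cis/trans classification of
    expression QTL, genomic interval overlap with a random-region permutation
    enrichment test, and a seeded simulator of the whole study design
    (pedigree, phenotypes, outlines, expression) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    IRanges,
    GenomicRanges,
    S4Vectors
Config/testthat/edition: 3
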