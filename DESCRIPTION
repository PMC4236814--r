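Package: geqtl
Title: Gene-Based Expression QTL Mapping with Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps expression quantitative trait loci (eQTL) in a gene-based
    framework: blocks of SNPs within a sequence-level gene (S-gene) are
    related to blocks of transcript probes of a transcript-level gene
    (T-gene) by partial least squares (NIPALS), with the number of genetic
    factors chosen by 7-fold cross-validated root mean PRESS and van der
    Voet's randomization test. Downstream tools identify
    ancestry-informative eQTL (exact 2xK allele-count tests with FDR
    control), ancestry-informative transcripts (a rank-score multivariate
    test), and compact ancestry-predictive SNP panels (forward selection
    inside linear discriminant analysis under nested 10-fold
    cross-validation). A synthetic-data generator (Balding-Nichols
    genotypes with planted cis/trans effects) supports end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mixOmics,
    optparse
Config/testthat/edition: 3
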