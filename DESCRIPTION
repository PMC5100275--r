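Package: radbias
Title: Allele Drop-Out Bias in RAD-seq Diversity Estimates
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@radbias.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@radbias.org>
Description: Coalescent simulation of RAD-seq experiments and quantification
    of the allele drop-out (ADO) bias in nucleotide diversity estimates.
    Simulates unlinked loci under panmictic, heterogeneous-theta
    ("selection") and two-population split models, performs in silico
    restriction digestion with random or named enzyme motifs, computes the
    pi_true / pi_RAD estimators and locus-sharing statistics, and corrects
    RAD-based diversity estimates by approximate Bayesian computation
    (rejection sampling with local linear regression adjustment). Also
    provides an in silico digestion front-end for reference-aligned phased
    genomes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stringi,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
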