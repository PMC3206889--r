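Package: genmix
Title: Genealogy-Based Mixed Model Association Mapping in Pedigreed
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide association mapping for complex pedigreed
    populations by combining local genealogies with a pedigree-based
    linear mixed model (GENMIX). Phased haplotypes are segmented into
    four-gamete-compatible intervals, a rooted binary perfect-phylogeny
    gene tree is built around each focal SNP, and cutting the tree at its
    top three levels yields up to seven haplotype clusterings that are
    tested as fixed effects in a REML linear mixed model with a pedigree
    numerator relationship matrix and Wald chi-square tests. The package
    also provides the single-SNP unified mixed model comparator, a
    gene-dropping simulator of pedigrees, phased markers and QTL
    phenotypes, and power and marker-ranking evaluation over replicated
    simulation designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    optparse,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
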