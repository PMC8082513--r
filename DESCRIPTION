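Package: studbook
Title: Pedigree-Based Population Structure and Genetic Diversity Analysis
    for Livestock Studbooks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the population structure, homozygosity and
    genetic diversity of domestic animal populations from studbook pedigrees.
    Computes pedigree completeness, equivalent complete generations,
    generation intervals, individual inbreeding coefficients (Meuwissen-Luo
    algorithm), individual increases in inbreeding and realized effective
    population size, pairwise and group-mean coancestry and numerator
    relationships, probability-of-gene-origin parameters (effective number of
    founders, founder genome equivalents via gene dropping, effective number
    of non-founders, expected-heterozygosity style diversity measures), and a
    founder decomposition of the mean inbreeding coefficient. Includes a
    synthetic studbook generator with overlapping generations, polygamous
    sires and breed-lineage labels for validating every estimator without
    access to confidential herdbook data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
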