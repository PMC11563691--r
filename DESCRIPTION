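Package: covshift
Title: Detecting Shifts in the Structure of Phylogenetic Trait Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects clade-level shifts in the structure of evolutionary
    covariation ("phylogenetic integration") among continuous traits on a
    dated phylogeny. Traits are reconstructed ancestrally under Brownian
    motion, branch-wise divergence vectors are formed, shrinkage-estimated
    correlation matrices summarise each regime, and a ranked greedy AIC
    search places covariation shifts on clades. Also includes a
    freezing-tolerance classifier from minimum coldest-month temperatures
    with Fitch parsimony mapping, and a simulator of regime-structured
    multivariate trait evolution for validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    phytools,
    optparse
Config/testthat/edition: 3
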