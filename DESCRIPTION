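Package: ccsallometry
Title: Phylogenetic Comparative Analysis of Cerebello-Cerebral Allometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogenetic comparative analysis of primate
    cerebello-cerebral volumetrics: evolutionary-model selection (Brownian
    motion, Pagel's lambda, Ornstein-Uhlenbeck, Early Burst) by maximum
    likelihood and AIC, ancestral character estimation of continuous traits,
    phylogenetic generalized least squares (PGLS) allometric regression with
    isometry tests, phylogenetic ANCOVA grade-shift tests, and a
    measurement-error robustness battery (within-brain and across-brain
    shrinkage simulations, provenance-subset comparisons, literature-based
    outlier filters). Includes a species-median volume table for 34 primate
    species, a synthetic time-calibrated consensus chronogram, and a
    synthetic-data generator (pure-birth trees, Brownian allometric traits,
    intraspecific specimen replicates) so every pipeline stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    withr
Config/testthat/edition: 3
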