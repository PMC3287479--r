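Package: pleiomine
Title: Multivariate Phenotype Pattern Mining and Pleiotropy-Aware GWAS
Version: 0.1.0
Authors@R:
    person("pleiomine", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage pipeline for discovering candidate pleiotropic loci
    from cohort data. Stage one discretizes an individual-by-trait table
    into quintile-coded items and mines multivariate phenotype patterns by
    APRIORI association rule mining with support/confidence/lift and
    rule-form constraint filtering, visualized as an undirected weighted
    trait graph. Stage two derives a case-control multivariate phenotype
    from the mined rules, runs allelic chi-square genome scans for the
    multivariate phenotype and each constituent single trait, and prunes
    SNPs acting on single traits using a log10 p-value ratio statistic
    (mOR) together with greedy LD clumping. Includes a synthetic
    genotype-phenotype simulator with planted effects so the whole
    pipeline is testable without cohort access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
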