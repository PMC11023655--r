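Package: duoburden
Title: Rare-Variant Gene Burden Tests with Maternal-Fetal Effect
    Decomposition for Birth Weight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end rare-variant collapsing burden analysis of birth
    weight in mother-child duos: genotype-level sequencing quality control
    (depth/genotype-quality filters, exact binomial allele-balance test,
    missingness and allele-depth regression filters), construction of
    protein-truncating and damaging-missense variant collapsing masks,
    covariate-adjusted per-gene carrier burden regression in fetal and
    maternal analysis arms, weighted-linear-model decomposition of the
    correlated marginal estimates into conditional fetal and maternal
    effects, and downstream inference (sex-dimorphism heterogeneity tests,
    conditional attenuation on GWAS sentinel dosages, exact sign-test
    replication concordance). Includes a Mendelian mother-child duo
    simulator with sequencing artifacts and messy phenotype reporting so
    the whole pipeline is testable without restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
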