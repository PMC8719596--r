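Package: smrmediate
Title: Summary-Data Mendelian Randomization with HEIDI Filtering and
    Methylation-Mediation Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates GWAS, cis-eQTL and cis-mQTL summary statistics by
    summary-data Mendelian randomization (SMR). For each molecular probe the
    top cis-QTL instruments a ratio estimate of the effect of the molecular
    phenotype on the trait; the HEIDI (heterogeneity in dependent instruments)
    test, evaluated over LD-pruned cis-SNP sets against a reference genotype
    panel, screens out associations driven by linkage rather than a single
    shared causal variant. Passing DNA-methylation and expression probes are
    combined into mediation models (SNP to methylation to expression to trait)
    with sign-consistency checks, Bonferroni multiple-testing control, gene
    overlap summaries and Fisher-exact tissue-specificity enrichment. A
    synthetic-data module simulates reference panels, molecular cohorts and
    trait cohorts with known causal architecture (mediation, pleiotropy,
    linkage, null) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
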