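Package: rarefib
Title: Rare Cardiomyopathy-Gene Variants and CMR-Quantified Myocardial Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tested pipeline linking rare, putatively pathogenic variants in a
    cardiomyopathy gene panel to interstitial myocardial fibrosis quantified by
    cardiac MRI T1 mapping. Implements rare-variant prioritization (panel,
    monomorphism, consequence, frequency, in-silico and ClinVar screens), an
    ACMG/AMP evidence-combining classifier with a phenotype-supported VUS+
    upgrade, extracellular-volume (ECV) phenotyping with a top-quartile case
    definition, carrier-enrichment statistics (two-sided exact test, odds
    ratio) and Monte-Carlo power estimation, together with a synthetic-cohort
    generator so every stage is testable without access to protected data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
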