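Package: cnaconcord
Title: Cross-Platform Copy-Number Concordance Analysis for SNP Arrays and MLPA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reimplements a SNP-array versus MLPA copy-number concordance
    analysis for acute lymphoblastic leukaemia as a tested pipeline: circular
    binary segmentation (CBS) of Log R Ratio data with permutation
    significance, categorical copy-number abnormality calling with an
    automated focal-rescue operator for events flanking probe-coverage gaps,
    MLPA peak-ratio calling with the adjacent-probe rule, a five-category
    discordance taxonomy, contingency tabulation with concordance
    percentages, and rule-based CNA-profile risk classification with
    reclassification counting. Includes a synthetic-cohort generator with
    known truth (coverage holes, subclonal attenuation, matched MLPA ratios)
    and packaged fixtures of the published contingency and discordance
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
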