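Package: methdrift
Title: Grade-Associated DNA Methylation Drift in Paired Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies CpG probes whose atherosclerotic-versus-normal
    methylation difference drifts with lesion histological grade in
    donor-paired methylation-array cohorts. Implements the logit (M-value)
    transform, per-probe Spearman rank-correlation screening of intra-pair
    M-value differences against grade with covariate screening and
    covariate-adjusted ANOVA, an extreme-grade effect-size filter, and a
    normal-tissue stability filter; plus genomic-context enrichment
    (gene compartments, CpG-island relation, baseline strata, SNP proximity,
    gene-set overlap), Ward biclustering of intra-pair differences, and
    cross-species methylation-expression and WGBS concordance integration.
    Ships a synthetic paired-cohort generator with planted ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
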