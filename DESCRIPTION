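Package: cciscore
Title: Confused Cell Identity Scoring for Squamous Epithelial Transcriptomes
Version: 0.1.0
Authors@R: person("cciscore", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Quantifies "confused cell identity" (CCI) in esophageal squamous
    cell carcinoma transcriptomes. Derives basal-stem (BS), proliferating
    basal-keratinocyte (BK) and differentiated-keratinocyte (DK) lineage
    signatures from labeled single-cell data by threshold-based marker
    calling, scores cells or bulk samples against the signatures, projects
    observations onto a BS-BK-DK ternary map, computes a cosine-law CCI
    score per observation, locates a cohort-level CCI positivity cut-point
    where the empirical CDF first crosses a fitted logistic curve,
    identifies CCI signature genes, and provides downstream association and
    survival statistics (correlation, rank tests, hypergeometric overlap,
    maximally selected log-rank cut-points, Kaplan-Meier stratification).
    Ships a negative-binomial synthetic cohort generator so the entire
    pipeline runs and validates without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
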