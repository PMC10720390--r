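Package: polyrisk
Title: Joint Rare-Variant and Polygenic Risk Score Modelling of Disease Risk
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combined rare-variant and polygenic risk score (PRS) analysis for
    case-control studies of prostate cancer and similar diseases. Provides
    rule-based classification of rare variants as pathogenic, likely pathogenic
    or deleterious (P/LP/D) from consequence class, ClinVar assertions and
    in-silico predictor consensus; carrier determination across a gene panel;
    weighted-sum PRS scoring with a polymorphic-variant filter and
    control-anchored tertile categories; six-category joint logistic
    odds-ratio estimation with covariate adjustment and multiplicative
    interaction tests; and absolute lifetime-risk estimation under competing
    mortality with case-mix odds-ratio weighting, prevalence-weighted category
    frequencies and Monte Carlo confidence intervals. A synthetic-cohort
    generator emulates the statistical structure the analysis assumes so the
    whole pipeline can be exercised without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
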