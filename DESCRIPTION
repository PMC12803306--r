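Package: phescore
Title: Phenotype Risk Scores for EHR-Based Rare-Disease Case Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates phenotype risk scores (PheRS) from
    longitudinal diagnosis-code data. Phenotype features are expert-curated
    groups of ICD-9/ICD-10 codes; per-feature weights are log inverse
    frequencies estimated in a reference ("training") population, and a
    patient's score is the sum of weights over features present in their
    record. Includes standard, negative-weight, and precomputed-weight
    scoring variants, hierarchy expansion of seed codes against a user
    catalog, target-disease code exclusion, case/control/training role
    assignment from genotype status, deployment stratification (age,
    race/ethnicity, feature history), and a prioritization-oriented
    evaluation suite (Wilcoxon rank-sum, Mann-Whitney AUC, precision-at-k
    with deterministic tie handling). A synthetic EHR cohort simulator with
    age-gated incomplete penetrance makes the full pipeline testable
    without access to restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
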