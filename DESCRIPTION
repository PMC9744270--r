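Package: adscreen
Title: Algorithmic Screening for Atypical Diabetes in EHR Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based computable phenotyping for atypical,
    insulin-sufficient non-metabolic diabetes in electronic health record
    (EHR) cohorts. Implements a base exclusion algorithm that removes
    typical type 2 diabetes (metabolic syndrome evidence, cystic
    fibrosis, positive islet autoantibodies) from a machine-learning
    flagged T2D group, six overlapping branch algorithms that rule out
    likely type 1 diabetes, a deterministic chart-review rule engine that
    assigns diabetes type and the KPD/MARD/ISNM atypical subtypes, allele
    dosage polygenic scoring with variant quality control, nonparametric
    cohort comparison statistics, and a seeded synthetic biobank cohort
    generator with calibrated phenotype-flag error structure for end to
    end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
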