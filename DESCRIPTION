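Package: crcqi
Title: Colorectal Cancer Surgery Quality Indicators from Registry and EMR Data
Version: 0.1.0
Authors@R:
    person("Maintainer", "crcqi", email = "crcqi@example.org", role = c("aut", "cre"))
Description: Computes colorectal-cancer-surgery quality indicators from two
    parallel patient-level datasets: a manually abstracted audit registry and a
    structured electronic medical record (EMR) extract. Indicators are
    represented as declarative numerator/denominator predicate trees evaluated
    under three-valued logic so that missing or unstructured data items yield
    an undetermined, never a silently wrong, result. Patients are linked across
    sources deterministically on gender, year of birth and operation date with
    procedure-set similarity as tie-breaker. Agreement between sources is
    quantified with diagnostic-accuracy statistics (sensitivity, specificity,
    predictive values, likelihood ratios) and a covariance-corrected z-test for
    proportions estimated from overlapping samples. Data quality is measured as
    per-item structured availability, completeness and cross-source
    effect-consistency (correctness). A synthetic paired-cohort generator with
    configurable degradation modes lets every stage run without access to
    protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
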