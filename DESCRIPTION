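Package: omopfreq
Title: EHR Concept Prevalence and Co-Occurrence Statistics from OMOP CDM Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes privacy-protected electronic health record (EHR)
    prevalence and patient-level co-occurrence statistics from OMOP Common
    Data Model style table extracts (person, condition_occurrence,
    drug_exposure, procedure_occurrence, concept). Patient counts of single
    concepts and concept pairs are filtered for rare counts, purged of
    iatrogenic codes, and perturbed by Poisson randomization before release.
    Concept associations are quantified by chi-square analysis, relative
    frequency, and the observed-expected log frequency ratio. Released
    statistics are written as tab-delimited flat-file bundles and served
    through an in-process JSON query interface. A synthetic OMOP cohort
    generator with configurable marginal prevalences and pairwise odds
    ratios makes the whole pipeline testable without access to clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
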