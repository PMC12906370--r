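Package: cogharmon
Title: Cross-Cohort Harmonization of Neuropsychological Test Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes longitudinal neuropsychological test scores across
    prospective aging cohorts that administer partially overlapping test
    batteries. Builds a merged participant-visit table over a shared test
    catalog, fills both sporadic and structural (test-never-administered)
    missingness with an iterative random-forest imputer, validates imputation
    precision with a mask-and-reimpute protocol benchmarked against
    test-retest discrepancy in cognitively unimpaired amyloid-negative
    participants, constructs standardized cognitive composites (PACC,
    episodic memory, executive function, language), and fits linear
    mixed-effects trajectory models across clinical-pathological groups
    defined by amyloid status and Clinical Dementia Rating. Includes a
    synthetic multi-cohort generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    lme4,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
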