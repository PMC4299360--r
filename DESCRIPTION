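Package: cowillis
Title: Morphological Typing and Population Statistics for the Circle of Willis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based morphological classification of the circle of Willis
    from per-subject cerebral-vessel measurements (ACA-A1 developmental status,
    anterior types I-V2, fetal-type posterior cerebral artery subtyping,
    posterior types a-k, and overall ring integrity), aggregation of classified
    cohorts into the standard cross-tabulations, and the associated
    contingency-table statistics: Pearson chi-squared without continuity
    correction, the linear-by-linear association trend statistic, and the
    tie-corrected rank-sum test on ordered categories.  Includes a seeded
    synthetic-cohort generator with class-conditional diameter models, CSV
    input/output for subject measurement tables, and a one-shot reproduction
    report against the published population values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
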