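Package: actipaq
Title: Accelerometer Data Reduction and Agreement with Physical Activity Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces epoch-level accelerometer count streams to intensity-classified,
    wear-time-adjusted daily minutes (non-wear detection by zero-run scan, counts-per-minute
    cut-points, valid-day and valid-subject rules); scores three physical-activity self-report
    instruments (IPAQ Short Form, the Tartu Physical Activity Questionnaire with its
    logit-scale MVPA index, and the Domain-Specific Impulsivity Inactivity scale); and runs
    the method-comparison battery relating them: descriptive statistics, log-scale Pearson
    correlation matrices with pairwise deletion, paired bias tests with activity-stratified
    splits, Bland-Altman limits of agreement with proportional-bias correlation, and
    multiple-regression prediction of objective MVPA. A seeded synthetic-cohort generator
    with exact ground-truth bookkeeping makes every stage testable without device files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
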