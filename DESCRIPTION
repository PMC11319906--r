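Package: adipometrics
Title: Anthropometric and Cardiometabolic Index Pipeline with
    Energy-Adjusted Nutrient Intake Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes ten body-composition and cardiometabolic indices
    (BMI, waist-to-height ratio, conicity index, body adiposity index,
    abdominal volume index, body roundness index, weight-adjusted waist
    index, lipid accumulation product, cardiometabolic index, atherogenic
    index of plasma) from anthropometry and fasting lipids; performs
    residual-method energy adjustment of nutrient intakes from repeated
    24-hour recalls with tertile stratification; provides tertile-wise
    ANOVA summaries, sex-stratified Pearson correlations,
    variance-explained regression, demographic tables, and
    finite-population sample-size calculation; and includes a seeded
    synthetic-cohort generator with a parameter-recovery harness so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    foreign
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
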