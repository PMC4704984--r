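Package: stepcea
Title: Cost-Utility Decision Modelling for Stepped-Care Depression Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic cost-utility model comparing internet-delivered
    cognitive behaviour therapy (myCompass), face-to-face CBT, and antidepressant
    treatment-as-usual for mild-to-moderate depression over a 28-week stepped-care
    horizon, from the perspective of the Australian health provider. Implements a
    four-cycle cohort decision tree evaluated by exhaustive path enumeration,
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves, one-way and threshold sensitivity analysis, expected value of
    (partial) perfect information, and a patient-level microsimulation engine
    that serves as a brute-force oracle for the cohort expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
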