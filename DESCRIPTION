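Package: tailcurve
Title: Long-Term Survival Award Rules over Kaplan-Meier Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Executable decision rules for the two oncology value-framework
    long-term survival awards: the ASCO Value Framework v2 tail-of-the-curve
    bonus (20 points for overall survival, 16 for progression-free survival)
    and the ESMO Magnitude of Clinical Benefit Scale v1.1
    immunotherapy-triggered long-term-plateau adjustments. Provides
    Kaplan-Meier step-curve estimation and queries (milestone survival,
    median, restricted mean survival time), an operational plateau detector,
    trial-cohort readers and writers, both award algorithms with per-criterion
    diagnostics, agreement statistics between the frameworks (Cohen kappa,
    McNemar test, risk differences with Wald intervals), and a
    mixture-cure-model trial simulator so the scoring rules can be validated
    against cohorts with known long-term survival structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
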