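Package: sealscore
Title: Emergency Department Workload and Crowding Score (SEAL)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the SEAL emergency department (ED) crowding score from
    patient event logs: fourteen workload variables evaluated over trailing
    one-hour windows, the published four-variable linear model on a 1-6 scale,
    the full derivation pipeline (univariate screening, collinearity check,
    multiple linear regression with p-value reduction and refit), the
    randomized assessment schedule generator, rater-agreement validation
    statistics, and a discrete-event ED simulator producing event logs, staff
    assignments and noisy workload assessments with known ground truth so the
    whole method is testable without real hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
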