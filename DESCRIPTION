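Package: kirchpk
Title: Kirchhoff's-Law Clearance Composition and Bioavailability Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for composing rate-defining pharmacokinetic clearances and
    rate constants in parallel and in series (the Kirchhoff's-law treatment of
    absorption-elimination kinetics), closed-form one-compartment extravascular
    models with and without gut-loss correction, non-compartmental analysis
    (AUC, MRT/MAT, renal clearance, bioavailability from AUC and urinary
    ratios), estimation of gut clearance from dual bioavailability
    measurements, paired crossover statistics, and a simulator for crossover
    bioavailability studies. Includes a packaged table of published crossover
    study summaries used to estimate gut clearance for nine drugs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
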