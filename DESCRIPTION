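Package: blinksed
Title: Blink-Reflex EMG Analysis of Sedation Depth During Propofol Induction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the electrically evoked blink reflex as a
    monitor of sedation depth during anaesthesia induction with propofol and
    remifentanil. Provides effect-site pharmacokinetic simulation of a
    constant-rate propofol infusion under the Schnider covariate model,
    synthesis of blink-reflex electromyogram sweeps with dose-dependent R1/R2
    attenuation, preprocessing and time/frequency feature extraction from the
    R1 and R2 analysis windows, the prediction probability (Pk) concordance
    statistic with jackknife standard errors, multinomial logistic modelling
    of an adapted Richmond Agitation-Sedation Scale, and detection of the
    loss-of-reflex and loss-of-responsiveness endpoints with cohort summaries.
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
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
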