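Package: mmgrowth
Title: Mother-Machine Single-Cell Growth-Rate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for mother-machine microfluidic cultivation
    data: reads division-event tables, corrects generation-time
    distributions for the finite-observation-window censoring bias, inverts
    them to population growth rates through the Euler-Lotka relation, fits
    Monod-type growth kinetics with Hill-type substrate inhibition across
    substrate concentrations, quantifies cell-to-cell heterogeneity, and
    estimates the diffusive transport limits of the growth channels. A
    synthetic-data generator simulates whole studies with known ground
    truth so every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
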