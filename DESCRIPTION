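Package: fallcoding
Title: Coding-Quality Assessment and Garbage-Code Correction for Elderly Fall Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the quality of ICD-10 cause-of-death coding for
    unintentional fall mortality among adults aged 65 years and older, and to
    correct it. Reads WHO Mortality Database style flat files and simplified UN
    World Population Prospects population tables, computes five problematic-code
    indicators (unspecified deaths; injury deaths with undetermined intent;
    unspecified unintentional injuries; falls with unspecified mechanism; falls
    with unknown occurrence place), redistributes the first three garbage-code
    types onto specific causes with an adaptive multi-year proportionate method,
    derives direct age-standardised fall mortality rates before and after
    correction with a six-tier impact classification, and quantifies how the
    correction changes 2005-versus-2015 comparisons and linear year trends. A
    synthetic-data generator produces flat files with known ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
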