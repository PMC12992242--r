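Package: cndc
Title: Critical Nitrogen Dilution Curves and Nitrogen Nutrition Diagnosis for Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and validating critical nitrogen
    concentration dilution curves (Nc = a * DW^-b) from multi-rate nitrogen
    fertilization field trials, diagnosing crop nitrogen status with the
    nitrogen nutrition index (NNI), and computing the downstream agronomic
    analytics that accompany such trials: nitrogen use efficiency indices,
    yield stability and sustainability indices, linear-plateau fits of
    relative yield on NNI, and the economic optimum fertilizer rate from a
    quadratic yield response. Includes a seeded synthetic randomized-block
    trial generator with a known ground-truth dilution curve so every stage
    of the pipeline can be tested by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    tools,
    utils,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
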