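Package: fermkin
Title: Growth and Lactic Acid Production Kinetics of Vegetable Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic analysis of spontaneous lactic acid vegetable
    fermentations such as gundruk. Provides the Modified Gompertz and
    Logistic primary growth models on the log10(N/N0) scale, the
    Luedeking-Piret family of product-formation rate laws (including
    total-product and undissociated-acid end-product inhibition),
    deterministic numerical integration of product concentration over a
    fitted biomass trajectory, bounded nonlinear least-squares parameter
    estimation, a goodness-of-fit battery (uncentered and conventional R
    squared, reduced chi squared, RMSE, RSS, MAPE) with an ordered
    model-selection rule, and a seeded synthetic fermentation-trajectory
    generator so the whole pipeline can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
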