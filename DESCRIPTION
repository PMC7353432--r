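Package: vitdfort
Title: Vitamin D Intake-Status Modelling and Cereal Fortification Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the relationship between daily vitamin D
    intake and serum 25-hydroxy-vitamin D status in survey populations, and
    for simulating the impact of vitamin-D-fortified ready-to-eat breakfast
    cereals on that status. Provides a saturating (asymptotic) dose-response
    model with closed-form inversion, a quadratic seasonal (UV-proxy) model
    of serum status by calendar month with analytic peak extraction, a
    counterfactual fortification engine with threshold-prevalence reporting,
    design-aware survey statistics (Taylor-linearized means, the adjusted
    Wald test, iterative Grubbs outlier screening), and a calibrated
    synthetic-cohort generator emulating the statistical structure of the UK
    National Diet and Nutrition Survey (2008-2012 waves) so the whole
    pipeline is testable without restricted microdata.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
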