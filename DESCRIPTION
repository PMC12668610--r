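Package: pushpull
Title: Push-Pull Modelling of Yeast Hexose-Transporter Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modelling of how budding yeast matches hexose
    transporter (HXT) expression to extracellular glucose. Provides an ODE
    model of the Snf3-Rgt2/SNF1 glucose-sensing network (Mth1, nuclear Std1,
    nuclear Mig1, Mig2, and a tagged Hxt), piecewise-linear glucose
    programmes, Hill-function promoter logic over all subsets of the four
    repressors, weighted least-squares calibration to time-lapse fluorescence
    with a seedable population-based optimiser, ABC-SMC (adaptive population
    Monte Carlo) model selection over promoter structures, bootstrap
    steady-state repression summaries, a binding-site occupancy-bias score,
    and a synthetic-data generator that emulates microfluidics fluorescence
    measurements and their normalisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
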