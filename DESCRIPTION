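Package: popproj
Title: Multi-State Provincial Population Projection and Gridded Downscaling
    Under Shared Socioeconomic Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A cohort-component projection engine for populations structured
    by province, sex, single-year age (0 to 100+) and seven education stages,
    with scenario builders encoding shared socioeconomic pathway (SSP)
    assumption trajectories for fertility, mortality, migration, sex ratio at
    birth and educational progression; life-table calibration of mortality
    schedules to life-expectancy targets and proportional calibration of
    fertility to total fertility rate targets; sigmoid (logistic) urbanization
    curve fitting and projection under fast/medium/slow assumptions; and a
    recursive dasymetric downscaler that allocates projected provincial urban
    and rural populations onto fine-resolution population grids using coarse
    urban-fraction layers. Includes a synthetic census-like world generator
    with known ground truth so every calibration step is testable, plus the
    accuracy metrics (percentage errors, RMSE, %RMSE, MAE, MAD) used to
    validate gridded population products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
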