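Package: shiftscreen
Title: Chemical-Shift Prediction from Computed Shieldings with DFT Method Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidy pipeline for predicting 1H and 13C NMR chemical shifts
    from quantum-chemistry isotropic shielding constants. Provides energy-window
    filtering and Boltzmann-weighted averaging over conformer ensembles, linear
    scaling of shieldings onto experimental shifts with inversion to predicted
    shifts, error statistics (MAE, RMSE, maximum absolute deviation, and
    percentage-of-range forms), and screening of density functional and basis-set
    combinations with deterministic ranking and best-per-functional selection.
    Ships readers for quantum-chemistry log files and tidy interchange tables, a
    synthetic-study generator with known ground truth for end-to-end testing, and
    the experimental assignment tables of a dammarane triterpenoid oxime as a
    worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
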