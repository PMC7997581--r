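Package: stereomatch
Title: Stereoisomer Assignment by Permutation Alignment of NMR Chemical-Shift Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns groups of stereoisomers by jointly comparing all available
    calculated and experimental 13C chemical-shift sets. Every permutation
    aligning the experimental sets to a fixed sequence of calculated sets is
    enumerated and scored with the mean absolute error of double shift
    differences (MAE_DDdelta), a statistic built from pairwise
    shift-difference sets that cancels systematic calibration error. Also
    provides the classic per-set Ddelta/MAE/RMSD diagnostics with a pluggable
    DP4-style probability backend, a Boltzmann conformer-averaging and
    multistandard-calibration pipeline turning isotropic shieldings into
    chemical shifts, and a seeded synthetic-data generator with known
    ground-truth permutation for validation.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
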