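Package: nusrd
Title: Non-Uniformly Sampled CPMG Relaxation Dispersion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, reconstruction and analysis of Carr-Purcell-Meiboom-Gill
    (CPMG) relaxation dispersion experiments recorded with non-uniform sampling
    (NUS). Generates synthetic two-state exchanging spin systems and their
    hypercomplex multidimensional time-domain data, designs exponentially
    weighted NUS schedules, reconstructs spectra by co-processed
    multi-dimensional decomposition (co-MDD) or by iteratively reweighted least
    squares with virtual-echo extension (IRLS-VE), quantifies peak intensity
    series into effective transverse relaxation rates, estimates per-peak errors
    by delete-d jackknife resampling and targeted-acquisition step differences,
    and fits global two-state chemical-exchange models (numerical
    Bloch-McConnell propagation and the Carver-Richards closed form).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
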