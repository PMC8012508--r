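Package: electrome
Title: Analysis of Plant Electrophysiological (EPG) Voltage Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing plant electrome recordings obtained by
    electrophytography (EPG): descriptive and dispersion statistics,
    autocorrelation and correlation time, FFT amplitude spectra, Welch power
    spectral density with power-law (1/f^beta) exponent estimation and noise
    colour classification, Morlet continuous wavelet scalograms, power-law
    tail fitting of the voltage-variation distribution, approximate and
    multiscale sample entropy, windowed feature extraction with PCA and a
    repeated stratified cross-validated classifier battery, and paired or
    independent group comparisons with normality-gated test selection. A
    seed-deterministic synthetic electrome generator (coloured 1/f^beta
    noise, slow undulation waves, heavy-tailed spike trains) supports
    desk-scale verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    ggplot2,
    e1071,
    kernlab,
    randomForest,
    rpart,
    class
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
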