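Package: nvucvr
Title: Grey-Box Modelling of Cerebrovascular Reactivity to Transcranial
    Direct Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic hypothesis testing of the fNIRS-measured hemodynamic
    response to transcranial direct current stimulation (tDCS). Implements a
    17-state nonlinear neurovascular-unit (NVU) simulator with four additive
    tDCS perturbation pathways (synaptic potassium, astrocytic transmembrane
    current, perivascular potassium, and smooth-muscle voltage-gated current),
    Jacobian linearization of the system at its baseline operating point into
    per-pathway grey-box state-space models, prediction-error fitting of those
    models to normalized total-hemoglobin time series with MSE/AIC scoring and
    residual diagnostics, balanced-truncation model reduction with
    minimal-realization transfer functions, fixed-order transfer-function
    estimation with chi-square nested-model comparison, an fNIRS
    preprocessing chain (tHb construction, PCA systemic removal, zero-phase
    band-pass, baseline normalization, anti-correlation QC, ensemble
    averaging), and a synthetic cohort generator so the full study design can
    be exercised without any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    signal,
    minpack.lm,
    Matrix,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
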