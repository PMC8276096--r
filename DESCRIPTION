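Package: escea
Title: Cost-Effectiveness Modelling of First-Line Chemo-Immunotherapy in
    Extensive-Stage Small-Cell Lung Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A partitioned-survival cohort model comparing first-line
    atezolizumab plus etoposide-platinum (AEP), durvalumab plus
    etoposide-platinum (DEP) and etoposide-platinum chemotherapy (EP) for
    extensive-stage small-cell lung cancer from a United States payer
    perspective.  Provides parametric survival curves (Weibull,
    log-logistic, exponential, log-normal, Gompertz) with hazard-ratio
    adjustment and pluggable long-term extrapolation, reconstruction of
    pseudo individual-patient data from digitized Kaplan-Meier curves with
    risk tables, censoring-aware maximum-likelihood fitting with AIC/BIC
    model selection, Bucher indirect treatment comparison, per-cycle cost
    and quality-adjusted life-year accrual, incremental
    cost-effectiveness ratios with dominance and efficiency-frontier
    analysis, one-way deterministic sensitivity analysis, price-reduction
    threshold search, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and a synthetic two-arm
    trial generator used for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    flexsurv,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
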