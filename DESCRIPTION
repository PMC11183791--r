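Package: vancopk
Title: Vancomycin Population Pharmacokinetics and Dosing Individualization
    in Obese Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-pharmacokinetic analysis pipeline for initial
    vancomycin therapy in obese adults. Implements body-size and renal
    covariate derivation (Du Bois BSA, Boer lean body mass, CKD-EPI eGFR),
    an analytic one-compartment infusion model with superposition, the
    final eGFR/LBM covariate model with lognormal inter-individual
    variability and additive residual error, Laplace and adaptive
    Gauss-Hermite marginal-likelihood estimation with stepwise covariate
    selection and nonparametric bootstrap, simulation-based diagnostics
    (PWRES, NPDE, VPC percentiles), Monte Carlo probability-of-target
    attainment for the AUC24 400-600 mg*h/L target, and a synthetic
    therapeutic-drug-monitoring cohort generator for sparse sampling
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
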