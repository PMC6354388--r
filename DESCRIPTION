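Package: geofgm
Title: Bayesian Geo-Additive Modelling of FGM/C Status in Household Surveys
Version: 0.1.0
Authors@R: person("geofgm", "maintainers", email = "geofgm@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing binary female genital mutilation/cutting
    (FGM/C) status from two-wave, two-stage cluster household surveys.
    Provides a DHS-like synthetic survey generator with known ground truth,
    descriptive prevalence tables and unadjusted odds ratios, a Bayesian
    geo-additive binary regression combining fixed effects, a penalized
    B-spline (second-order random walk) nonlinear age effect and structured
    (intrinsic CAR) plus unstructured regional spatial effects fitted by a
    Polya-Gamma data-augmentation Gibbs sampler, and posterior summaries:
    posterior odds-ratio tables, credible curves, significance-classified
    region maps and between-wave comparisons with split-region
    harmonization.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    splines,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
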