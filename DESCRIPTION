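Package: sharedcap
Title: Tumor Growth and Metastasis Models with a Systemically Shared Carrying Capacity
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Coupled Gompertz, logistic and exponential growth models for two
    tumors competing for one host-level carrying capacity, and a primary-tumor
    plus size-structured metastasis model in which every lesion draws on the
    same systemic capacity. Includes exact closed forms, an adaptive
    Runge-Kutta simulator with a characteristics/renewal reduction of the
    metastasis transport equation, an upwind finite-volume oracle, particle
    swarm calibration with nested group/subject parameter sharing, BIC model
    selection, relative standard errors, profile-likelihood identifiability,
    ratio/Bland-Altman and rank-test analyses, synthetic data generators for
    caliper series and endpoint nodule tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
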