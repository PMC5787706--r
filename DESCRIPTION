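Package: galnet
Title: Stochastic Modelling and Allele-Specific Parameter Inference for
    the Yeast Galactose Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how natural alleles of the yeast GAL3 gene shape
    the dynamics of galactose network induction. Provides an exact stochastic
    (Gillespie) simulator of a four-gene telegraph-promoter model with
    positive and negative feedback, a deterministic mean-field companion with
    bistability scans and a gradual/binary phenotypic landscape, flow-cytometry
    distribution statistics (density gating, plate-effect normalisation,
    Gaussian mixture amplitude, equal-misclassification ON/OFF threshold and
    inducibility), grid chi-squared inference of the GAL3 strength rho_Gal3
    and the galactose activation constant K_gal, and a synthetic cytometry
    data generator so that the whole gating-statistics-inference pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    rlang,
    generics,
    stats,
    utils,
    deSolve,
    pracma,
    MASS,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
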