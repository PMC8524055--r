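Package: mpqtl
Title: Systems Mapping of Multiphasic Growth QTLs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Functional/systems mapping of quantitative trait loci (QTLs)
    that control the covariation of two longitudinal growth traits across
    developmental phases. Genotype-specific mean trajectories follow a
    biphasic nonlinear governing equation: a Lotka-Volterra-coupled pair of
    logistic curves for the juvenile phase plus Gompertz curves for the
    adult phase. Residuals follow a first-order structured antedependence
    (SAD(1)) covariance over the bivariate time grid. The package fits the
    no-QTL and genotype-specific models by EM with Nelder-Mead M-steps,
    scans markers with likelihood-ratio tests under Bonferroni and
    Benjamini-Hochberg correction, decomposes genetic effects and
    phenotypic variance explained over time, and provides a full
    simulation engine for power, false-positive rate, ROC/AUC, and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
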