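Package: twotypeSFS
Title: Site Frequency Spectra in Two-Type Branching Models of Tumor Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the site frequency spectrum (SFS) of an
    exponentially growing tumor under the two-type branching-process model of
    clonal evolution. A resident type-0 population with net growth rate
    lambda0 seeds fitter type-1 subclones (growth rate lambda1 > lambda0) at
    rate u1 per cell, while neutral mutations accumulate at rate nu under the
    infinite-sites model. The package provides the closed-form analytic layer
    (median time of the first successful driver, the limiting Poisson
    intensity of subclone sizes, the 1/f^alpha spectrum of driver mutations
    with alpha = lambda0/lambda1, subclonal-driver detectability under the
    fixed-final-size parameterization), Poisson-Dirichlet PD(alpha, 0)
    sampling of relative subclone sizes by two independent constructions, an
    exact Gillespie birth-death-mutation simulator, fast hybrid simulators for
    large populations and for normally distributed random fitness increases,
    and least-squares fitting of empirical spectra to the neutral 1/f and the
    selective C/f^beta shapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
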