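Package: peakdrift
Title: Prevalence Peak Drift of Chronic Diseases on the Lexis Plane
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates and propagates the age-specific prevalence peak ("trace")
    of a chronic disease over calendar time on the Lexis plane.  Implements two
    complementary routes: a transport-equation route for the illness-death
    model, in which prevalence is integrated along characteristics (a Riccati
    ordinary differential equation) from incidence and mortality rate fields,
    with the peak trace obtained either by per-year peak extraction or by an
    implicit-function-theorem ODE; and a logistic-polynomial route, in which
    expit of a cubic-in-age, linear-in-time polynomial is fitted to aggregated
    prevalence counts by binomial maximum likelihood, the trace is obtained in
    closed form from the roots of the age derivative, and uncertainty is
    quantified by a parametric bootstrap.  Also computes the on-trace
    proportionality between the age slope of incidence and the age slope of
    excess mortality, including its perturbation term.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
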