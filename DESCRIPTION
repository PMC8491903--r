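Package: evorescue
Title: Optimal Dosing Against Drug-Induced Evolutionary Rescue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the evolutionary rescue of a drug-sensitive cell
    population through dose-dependent resistance mutation, and optimises
    dosing schedules against it. Provides a two-type birth-death-mutation
    model with Hill pharmacodynamics and a linearly dose-dependent mutation
    rate, rescue-probability and discounted cost functionals, three
    optimal-control solvers (implicit stationary control law, a
    forward-backward sweep implementing Pontryagin's minimum principle, and
    a Hamilton-Jacobi-Bellman grid solver), an exact Gillespie simulator of
    virtual treatments with per-lineage establishment tracking, and scripted
    experiments for intensity profiles, mutagenicity-dose contours, and
    stochastic dose sweeps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
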