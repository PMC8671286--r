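Package: p62aggr
Title: Kinetics of p62-Ubiquitin Aggregates in Autophagy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the condensation of ubiquitinated cargo by oligomers of
    the autophagy receptor p62 (SQSTM1). An aggregate is described by the
    counts of one-hand bound cross-linkers, both-hand bound cross-linkers
    and p62 oligomers, either as a discrete continuous-time Markov chain
    simulated exactly (Gillespie direct method) or, in the large-aggregate
    scaling, as a three-dimensional mass-action ODE system. The package
    computes the closed-form regime parameter separating dissolution,
    finite limiting size and unbounded quadratic-in-time growth, the
    explicit non-trivial steady state, quadratic-growth coefficients from
    formal asymptotics, the cross-link-conserving limit with its Lyapunov
    diagnostic, and concentration-space bifurcation curves used to estimate
    the p62-ubiquitin dissociation constant from aggregation-onset
    concentrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
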