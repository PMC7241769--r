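Package: ednaopt
Title: Protocol Optimization for Environmental DNA Assays
Version: 0.1.0
Authors@R:
    person("Estuarine", "Genomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing factorial
    environmental DNA (eDNA) protocol-optimization experiments in which
    water samples pass through filtration, DNA extraction, optional
    secondary PCR-inhibitor removal (SIR) and quantitative PCR. Provides a
    seeded generator for synthetic multi-step recovery experiments with
    censored qPCR detection; standard-curve quantification utilities; a
    Bayesian decomposition of total yield into per-step capture,
    extraction and inhibitor-carryover fractions fitted by automatic
    differentiation variational inference (with an adaptive MCMC
    cross-check); WAIC and Pareto-smoothed importance-sampling LOO model
    comparison with pseudo-BMA and stacking weights; random-forest step
    importance; and cost/time/yield protocol ranking with a configurable
    decision-rule engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    optparse
Config/testthat/edition: 3
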