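Package: hubsens
Title: Sensitivity Trends Across Reproducible Parameter Sets in Signaling Hub Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and local sensitivity analysis of four canonical
    signaling-hub motifs (reversible reaction, cycle, negative feedback loop,
    incoherent feedforward loop) driven by ten time-varying input signal
    patterns. Generates replicate ensembles of stochastic trajectories with the
    chemical Langevin equation (Euler-Maruyama), scores candidate kinetic
    parameter sets against the ensemble summaries with a scale-invariant cosine
    fitness, collects diverse reproducible ("positive") parameter sets by
    log-uniform sampling and a genetic local search, computes local
    log-sensitivities of the output time integral by forward finite differences,
    and summarises how relative sensitivity strengths behave across the
    reproducible ensemble (principal components, per-set z-scores, pairwise
    dominance percentages, log2 sensitivity ratios, integral-sensitivity
    correlations).
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
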