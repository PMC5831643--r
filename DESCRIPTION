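Package: trustgame
Title: Interactive POMDP Modelling of the Multi-Round Trust Game
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generative modelling of dyadic behaviour in the 10-round
    economic trust game. Implements a level-k interactive partially
    observable Markov decision process (I-POMDP) with Fehr-Schmidt
    inequality-aversion (guilt) utilities, investor social risk aversion,
    Dirichlet-multinomial opponent inference, and irritation-driven internal
    state shifts with rupture and repair dynamics. Provides deterministic
    shared-tree planning, dyad simulation (free-running and scripted),
    per-subject maximum-likelihood fitting over discrete parameter grids,
    likelihood-ratio and BIC model comparison, parameter-recovery studies,
    and a model-based classifier of 'perilous' trustees.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
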