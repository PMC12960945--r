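Package: rangesweep
Title: Selective Sweep Probabilities in Spatially Expanding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and simulation tools for studying whether beneficial
    mutations sweep to fixation during range expansions. Implements a
    macroscopic constant-radial-speed model (Weibull laws for the arrival time,
    radius and location of the first surviving mutant; exact and closed-form
    conditional and unconditional sweep probabilities in one, two and three
    dimensions; posterior radius given a sweep; FKPP speed mapping and
    tumour-scale unit conversion), sweep and envelopment probabilities for
    alternative growth laws, a two-dimensional deme-based spatial Moran
    (stepping-stone) agent-based simulator with fixed or random multiplicative
    mutation effects, and the batch statistics that link the two, including a
    right-truncated-gamma undercount correction for sweeps unfinished at the
    simulation stop time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
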