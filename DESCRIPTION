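Package: evofoodweb
Title: Eco-Evolutionary Food-Web Assembly with Invader Strangeness Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates the assembly of multi-trophic food webs on a continuous
    body-size trait axis. Species carry three heritable traits (body mass,
    feeding center, feeding range) that set attack rates through Gaussian
    feeding kernels; biomass dynamics follow an allometrically scaled
    bioenergetic consumer-resource model with interference competition derived
    from kernel overlap. New species enter at fixed intervals as mutants of
    abundant residents or as invaders whose trait novelty is controlled by a
    strangeness parameter, and populations falling below an extinction
    threshold are removed. The package provides the simulator (with a compiled
    adaptive Runge-Kutta-Fehlberg integrator), a parameter-sweep driver over
    invader strangeness, disturbance and diet-breadth metrics (biomass
    variability, species turnover, fundamental and realized feeding range,
    lifespan regressions), and a small trend-analysis layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    yaml
Config/testthat/edition: 3
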