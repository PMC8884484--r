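Package: chase
Title: Markov-Chain Model of Migration Driven by Changing Mindset,
    Agglomeration, Social Ties, and the Environment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates population movement between cities with a
    column-stochastic Markov chain whose transition probabilities combine
    a gravity-style distance deterrent, an agglomeration benefit with a
    time-varying exponent (the "changing mindset" schedule), social-tie
    homophily in destination choice, and Ricker-type environmental
    pressure (the CHASE drivers). Provides deterministic expected-flow
    and stochastic multinomial dynamics, random city-map generation,
    inverse Simpson diversity and surviving-city metrics, seeded ensemble
    experiments (characteristic-size sweeps, social-tie diversity
    analyses, legacy-effect comparisons), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
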