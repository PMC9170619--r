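Package: coalsim
Title: Simulation and Analysis of Three-Player Weighted Majority Coalition Games
Version: 0.1.0
Authors@R:
    person("coalsim", "developers", email = "coalsim@example.org",
           role = c("aut", "cre"))
Description: A desk-scale engine for experimental coalition formation research.
    Defines simple weighted majority games (resource vectors, a decision point,
    a fixed payoff), implements the two classic three-player bargaining
    protocols -- the one-step display procedure and the alternative-offers
    procedure with tentative coalitions and ratification -- and runs them with
    configurable software agents (equity-proportional, equal-split, random,
    timeout) standing in for human participants. A batch session runner
    assigns resources randomly or by earned effort rank, models participant
    dropout, and writes replayable outcome and event tables. A statistics
    module provides coalition frequency tables, the chi-square goodness-of-fit
    test, Cohen's w, noncentral chi-square power and minimum detectable effect
    size, odds ratios, and Cohen's d for comparing observed coalition
    distributions against theoretical benchmarks.
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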