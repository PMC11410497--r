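Package: drinkdom
Title: Social Dominance Hierarchies from Automated Drinker and Feeder Visit Logs
Version: 0.1.0
Authors@R: person("Devin", "Kask", email = "dkask@posteo.net", role = c("aut", "cre"))
Description: Tools to infer social dominance hierarchies in dynamic dairy-cow
    groups from electronic water- and feed-bin visit logs. Detects agonistic
    replacement events from short exit-to-entry gaps at a bin, scores animals
    with sequential Elo ratings over a changing roster, summarises dominance
    as summed winning probabilities with resampling-based uncertainty and
    hierarchy steepness, partitions days into hot and normal periods from the
    temperature-humidity index (THI), computes daily and diurnal-block
    drinking metrics, and tests dominance-behaviour associations with
    Spearman correlations, Welch's t-test and Benjamini-Hochberg adjustment.
    Includes an agent-based herd simulator that emits the same log formats
    with known ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
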