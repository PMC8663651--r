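Package: painlex
Title: Mining Contemporary Pain Descriptors from Social Media Text
Version: 0.1.0
Authors@R:
    person("painlex", "developers", email = "painlex@example.org", role = c("aut", "cre"))
Description: Tools for mining contemporary pain vocabulary from social media
    style corpora and revising a multidimensional pain questionnaire. Implements
    a two-round text-mining workflow: hop-limited relevance filtering on word
    co-occurrence graphs, rule-based sarcasm exclusion, skip-gram word
    embeddings with nearest-neighbour candidate-descriptor discovery and
    pruning, lexicon-based emotion-intensity scoring, and a revision engine
    that applies count-threshold, addition, psychological-subclass and
    intensity-reordering rules to the 78-descriptor, 20-subclass McGill Pain
    Questionnaire. Ships a seeded synthetic-corpus generator with planted
    lexical structure so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
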