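Package: xsitlearn
Title: Cross-Situational Word Learning by Reinforcement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates an agent that learns word-object mappings from
    ambiguous caregiver-infant interactions by reinforcement. Each learning
    situation pairs an utterance with the visible objects and the single
    jointly-attended object; choosing a word is an internal action rewarded
    when consistent with attended-object transitions (novel names map to
    novel objects). Provides tabular learners (Q-learning, SARSA,
    SARSA-lambda), neural learners (online Q-network, neural fitted Q, deep
    Q-network with experience replay and a target network), binary and
    prosodic pitch-prominence utterance encodings, a synthetic
    caregiver-infant corpus generator with planted gold lexicons, and
    precision/recall/F-score lexicon evaluation with threshold sweeps and a
    co-occurrence baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
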