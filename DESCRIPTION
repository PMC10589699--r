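Package: alignsim
Title: Cross-Modal Systems Alignment in Simulated Concept Learners
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates agents that acquire cross-modal concept knowledge
    (word-object mappings) and infer novel mappings by aligning the
    similarity structure of a visual and a linguistic embedding system.
    Provides readers for GloVe-dialect embedding files and MB-CDI /
    WordBank item-trajectory tables, Spearman-based alignment scoring and
    two-alternative forced-choice evaluation, month-by-month
    vocabulary-growth simulation for age-of-acquisition and control
    agents, structural characterization of knowledge states
    (neighborhood-graph degree, distance and dimension-coverage features)
    with a recursive-feature-elimination logistic classifier, and
    generative agents that learn target feature values and weights by
    gradient descent to select concepts via softmax sampling. A synthetic
    paired-embedding generator with planted cluster structure and
    density-biased acquisition schedules makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
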