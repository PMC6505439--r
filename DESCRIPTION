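Package: banditmeta
Title: Confidence-Guided Exploration and Metacognition in Two-Armed Bandit Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for value-based learning experiments in
    which participants play a two-armed bandit with beta-distributed rewards while
    reporting value beliefs, belief confidence, and decision confidence. Provides a
    generative task environment (blocked designs with rating/choice trial mixes),
    confidence-augmented learning agents (ideal observer, delta-rule reinforcement
    learning, and a particle filter), cohort simulation with known ground truth, the
    preprocessing rules used for such data (reaction-time exclusion, carry-forward of
    ratings, exploration and accuracy labelling, within-subject standardization and
    quantile binning), hierarchical mixed-effects regressions of decision confidence,
    exploration, and belief confidence, repeated-measures trend ANOVAs with
    Greenhouse-Geisser correction, per-subject meta-d' metacognitive efficiency by
    maximum likelihood, and likelihood-based agent model fitting with BIC comparison
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    Rcpp,
    yaml,
    jsonlite,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
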