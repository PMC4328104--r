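Package: agemodel
Title: Age-Structured Animal Models for Cross-Fostered Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Restricted maximum likelihood (REML) estimation of maternal
    age-specific additive genetic variance with the animal model, designed
    around split-brood cross-fostering experiments in wild passerines.
    Provides pedigree handling (validation, topological sorting, pruning,
    and the numerator relationship matrix), a dense-matrix REML engine
    supporting group-structured genetic covariances (homogeneous,
    rank-one with correlation fixed at unity, and unstructured 2x2),
    nested likelihood-ratio model ladders with boundary-aware mixture
    p-values, narrow-sense heritability with delta-method standard
    errors, and a synthetic-data generator that emulates a
    quartet-matched, split-brood cross-fostering and brood-size
    manipulation design, including optional extra-pair-paternity
    pedigree corruption, so that every stage of the analysis is
    verifiable by simulation and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
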