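Package: rpnsig
Title: Resting-State Connectome Signatures of Pain Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and validating sparse functional-connectome
    signatures of individual pain sensitivity. Covers quantitative sensory
    testing (QST) threshold computation and composite pain-sensitivity
    scoring, head-motion quality control (Power framewise displacement,
    Friston-24 expansion, scrubbing), regional-timeseries cleaning (CompCor
    components, nuisance regression, bandpass filtering), shrinkage-based
    partial-correlation connectome estimation, a robust-scaling / K-best /
    elastic-net predictive pipeline with leave-one-out hyperparameter search
    and learning curves, signature extraction and external application, and
    permutation and bootstrap inference. A synthetic-cohort generator with a
    planted sparse connectivity-trait structure makes every stage testable
    end to end, and the published 21-connection resting-state pain
    sensitivity network (RPN) signature ships as a fixture.
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
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
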