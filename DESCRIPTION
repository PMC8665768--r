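Package: sivsel
Title: Stable Iterative Variable Selection for Binary Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stable feature selection for binary outcomes by aggregating an
    ensemble of cross-validated L1-penalized logistic regressions fitted under
    many random fold assignments. Per-feature variable-importance (VIMP)
    scores combine selection frequency, sign consistency and coefficient
    magnitude; a recursive feature-elimination pass ordered by increasing
    VIMP, together with a strictness-controlled AUROC cutoff, yields a
    compact and reproducible feature set. Includes a synthetic-data
    generator with known informative features, evaluation statistics
    (AUROC, paired DeLong test, paired Wilcoxon, selection-stability
    summaries), a stability study harness, plotting helpers and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ggplot2,
    optparse,
    stats,
    utils,
    parallel,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
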