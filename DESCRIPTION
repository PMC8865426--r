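Package: snmtf
Title: Multi-Omics Subtyping via Masked Symmetric Non-Negative Matrix
    Tri-Factorization of Patient Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates multiple omics layers measured on a shared sample
    roster by building one locally-scaled patient-similarity network per
    layer, jointly tri-factorizing the similarity matrices A_i ~ H S_i H'
    with a shared non-negative factor H under an availability mask and a
    sparsity penalty, and assigning robust consensus cluster labels through
    resampled factorizations, residual-weighted consensus matrices, and
    Normalized-Cut partitioning. Model selection is supported through the
    proportion of ambiguously clustered pairs (PAC) and the cophenetic
    correlation coefficient (CCC). Includes per-layer preprocessing
    (missing-value filtration, methylation M-value transform, a log-based
    count transform, feature standardization), single-layer spectral
    clustering with eigengap rank selection, external cluster-agreement
    indices, a boosted-stump feature-attribution module for marker
    discovery, a synthetic Gaussian-blob cohort generator for validation
    experiments, and a four-subcommand command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
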