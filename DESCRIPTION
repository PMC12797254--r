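Package: neuroverlap
Title: Conjunction and Representational Similarity Analysis of Two-Task
    Block-Design fMRI with a Synthetic BOLD Generator
Version: 0.1.0
Authors@R:
    person("neuroverlap", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for testing within-participant neural overlap between two
    cognitive tasks in block-design fMRI. Implements a synthetic BOLD
    generator with known activation geometry and controllable cross-condition
    pattern correlations; ART-style outlier detection and first-level GLM
    fitting with contrast t-maps; group-level conjunction analysis with
    Monte-Carlo cluster-extent correction; ROI-based representational
    similarity analysis with Steiger's Z contrasts of dependent correlations
    and Dunn-Sidak correction; and multivariate noise normalization with
    split-half cross-validated pattern similarity. Includes lightweight
    NIfTI-1 and BIDS-style TSV input/output and a reproducible end-to-end
    pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
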