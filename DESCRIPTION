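Package: threatrsa
Title: Model-Based Trial-by-Trial Representational Similarity Analysis for
    Social Threat Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based trial-by-trial representational similarity
    analysis (RSA) of event-related fMRI from a 2 (partner intentionality) x
    2 (CS type) social threat-learning paradigm. Generates and validates
    target/filler trial schedules, simulates single-trial voxel patterns,
    BOLD timeseries and pupil traces with planted effects, estimates
    single-trial beta patterns with a least-squares-all GLM, builds
    condition-grouped representational similarity matrices over target
    trials, constructs hypothesis-shaped template regression matrices
    (category, intentionality, CS type, and learning/extinction ramps),
    fits the per-subject template regression on Fisher-transformed
    similarity values, and performs group inference with Benjamini-Hochberg
    false-discovery-rate correction across regions of interest. Also
    includes the consecutive-trial correlation analysis with a 2x2
    repeated-measures ANOVA and a pupillometry preprocessing pipeline
    (blink repair, baseline correction, peak extraction, trial and
    participant quality control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
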