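Package: longdcm
Title: Longitudinal Diagnostic Classification Models with Hierarchical
    Attributes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and simulation tools for longitudinal diagnostic
    classification models. Implements the transition diagnostic
    classification model (TDCM), a latent transition model whose
    measurement component is the log-linear cognitive diagnosis model
    (LCDM), and its hierarchical variant (H-TDCM) in which an attribute
    prerequisite hierarchy restricts the latent profile space and fixes
    redundant item parameters at zero. Provides attribute-hierarchy
    utilities (reachability matrices, permissible profile enumeration),
    Q-matrix design constructors and identifiability diagnostics
    (Gamma-matrix separability, reachability-block counting, attribute
    coverage), marginal maximum likelihood estimation via EM with the
    forward-backward algorithm, MAP classification, likelihood-ratio
    model comparison, a seeded response simulator, and a Monte Carlo
    study runner reporting profile and marginal correct classification
    rates.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
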