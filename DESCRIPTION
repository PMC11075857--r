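Package: upliftrules
Title: Interpretable Treatment-Effect Subgroup Discovery with Uplift Forests and Rule Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies responsive patient subgroups from randomized trial data
    by growing an ensemble of uplift trees that split on the Kullback-Leibler
    divergence between arm outcome distributions, flattening the forest into
    candidate decision rules, and selecting a complementary, ranked rule set
    with an L1-regularized linear model fit to the forest's heterogeneous
    treatment effect estimates. Small trials can be augmented with
    eligibility-filtered historical controls and generator-produced synthetic
    subjects, re-balanced by elastic-net propensity scores with caliper
    nearest-neighbor matching. Includes Qini-coefficient evaluation,
    covariate-balance and synthetic-data similarity diagnostics, and a
    simulation module with planted rule-defined subgroups for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml,
    MASS,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
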