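Package: leakybeta
Title: Aversive Learning Models, Uncertainty, and Gaze Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling concurrent aversive (shock-probability) learning
    about multiple stimuli and its interplay with visual selective attention.
    Implements a family of trial-level belief-update rules (Rescorla-Wagner
    variants, Pearce-Hall hybrids, and leaky beta-distribution learners with
    optional attention coupling), a synthetic task and cohort generator,
    hierarchical Bayesian model fitting with WAIC and block-wise cross-validation,
    fixation-bias processing, and hierarchical beta/linear regressions linking
    model-derived value and uncertainty to gaze.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, coda, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), rjags, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
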