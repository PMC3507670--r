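Package: quitmiss
Title: Selection and Repeated-Attempts Models for Missing Binary
    Outcomes in Smoking Cessation Trials
Version: 0.1.0
Authors@R:
    person("iQuit", "Methods Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for exploring the missing-data mechanism for a binary
    trial outcome, motivated by Internet-based smoking cessation trials
    with heavy loss to follow-up.  Implements a logistic selection model
    whose full marginal likelihood sums the unobserved outcome out of the
    nonresponder contributions, a sensitivity analysis over a fixed
    outcome-missingness log odds ratio with conversion to the
    informatively missing odds ratio (IMOR) scale, a repeated-attempts
    (attempt-level) model of nonresponse with per-attempt intercepts, and
    Bayes posterior predictions of the unobserved outcome for
    nonresponders.  A synthetic-cohort generator with known ground truth
    supports end-to-end validation without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
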