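Package: voteframe
Title: Simulation and Inference for Goal-Framed Voting and Opt-Out Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the framing of a voting decision
    (selecting the better candidate versus rejecting the worse one) shapes
    the decision to opt out of voting. Implements an issue-alignment
    desirability score for hypothetical candidates, a constrained ballot
    generator that balances issue occurrence and counterbalances candidate
    position, logistic-model voting agents that choose or abstain under
    either goal frame, fixed-effects regression fits with participant-level
    exclusion and standardization rules, parameter-recovery experiments,
    deterministic expected-vote election scenarios, and the two-proportion
    z test with continuity correction used for framed poll comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
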