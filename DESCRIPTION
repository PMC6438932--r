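Package: pufval
Title: Personal Utility Functions for Health-State Valuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Constructs personal utility functions (PUFs) over a three-level,
    five-dimension EQ-5D-style health-state space from structured elicitation
    responses (dimension ranking, swing ratings, level point allocations and
    choice tasks); generates the adaptive interview tasks the elicitation
    protocol requires (tailored validation pairs, a bisection search for the
    personal location of dead, interaction checks); anchors each respondent's
    utilities at dead = 0; and aggregates personal utility functions into a
    social value set. Includes a configurable simulator of synthetic
    respondents for end-to-end and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
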