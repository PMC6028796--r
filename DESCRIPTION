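Package: mciid
Title: Low-Tech Identification Codes for Mass Casualty Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encoder, decoder and validator for a 16-character alphanumeric
    casualty identification code that first responders can create by hand at
    a disaster scene, combining a 7-character responder block (job category,
    name initials, age, wrapping serial triage number) with a 9-character
    casualty block (day/hour/minute of triage, age decade, gender, name
    initial, with 'u' marking unknown values). Also provides duplication-rate
    statistics for ID lists, an analytic structured-birthday-problem collision
    model, and a seeded Monte Carlo simulator of desk-based mass-casualty
    triage exercises with synthetic responder rosters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
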