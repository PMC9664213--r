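Package: pedpip
Title: Screening of Potentially Inappropriate Prescribing in Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A machine-readable knowledge base of 136 explicit criteria for
    detecting potentially inappropriate prescribing (PIP) in pediatric
    patients, together with a rule engine that screens structured
    prescription records for potentially inappropriate medications (PIM)
    and potential prescribing omissions (PPO) under three-valued logic, a
    modified-Delphi consensus calculator for criteria development, and a
    seeded synthetic prescription cohort generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
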