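Package: dyadscreen
Title: Verification and Validation of Dyadic Online Screener Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A data-quality pipeline for couple-based online studies that
    recruit both members of a dyad through a web eligibility screener.
    Provides eligibility screening against individual inclusion criteria,
    linkage of partner entries via referral tokens with a contact
    cross-reference fallback, rule-based verification that two screener
    entries describe a real relationship (concordance of relationship
    length, birthday months, ages, and contact information), and post hoc
    fraud-flag validation that the two entries come from two unique
    individuals (shared IP addresses, eligibility fishing, sequential
    email accounts, back-to-back completions with near-identical
    responses, and duplicate couple enrollments). Includes a seedable
    synthetic-cohort generator with labeled ground truth so the whole
    pipeline can be exercised without real participant data, plus a
    command-line interface and JSON/CSV reporting for manual-review
    triage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
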