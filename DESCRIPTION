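Package: callexchange
Title: Temporal Structure of Vocal Exchanges in Paired Songbirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the temporal structure of contact-call
    exchanges between paired birds. From annotated call-event tables (CSV or
    Raven selection tables) the package builds exchange and repeated call
    transitions, decomposes log10 inter-call intervals into short "response"
    and long "independent calling" components with a two-component Gaussian
    mixture fitted by expectation-maximization, compares fitted components
    across conditions with a parametric Monte-Carlo percentile-interval test,
    constructs a pair-preserving session-shuffle (pseudo-turn-taking) null,
    models per-phase call counts with Poisson mixed models, validates
    annotator agreement, and simulates reactive two-bird calling sessions so
    every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
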