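Package: abrkit
Title: Auditory Brainstem Response and Binaural Interaction Component Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying auditory brainstem response (ABR)
    recordings in rodents: epoch-level artifact rejection and averaging,
    zero-phase band-pass filtering and baseline zeroing, automatic wave I-IV
    peak/trough detection with manual-override support, audiogram and click
    hearing-threshold estimation, extraction of the binaural interaction
    component (DN1) across interaural time differences, derived pinna
    morphometrics, and a mixed-effects group-comparison layer with estimated
    marginal means.  Ships a synthetic ABR generator with full generative
    truth bookkeeping so every stage of the pipeline can be validated
    end-to-end without recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
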