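Package: ofcalc
Title: Observational-Fear Calcium Imaging Event Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and classification of calcium transients recorded
    from mouse anterior cingulate cortex during an observational-fear
    protocol. Implements threshold-based transient ("spike") detection
    from 20 Hz fluorescence traces, a circular temporal-shift shuffle
    null for identifying shock-responding and shock-suppressed cells,
    assessment of optogenetic suppression during light-ON trials,
    freezing-bout behavioral metrics, and the associated summary
    statistics. Ships a synthetic-session generator with planted ground
    truth so the whole pipeline is testable without raw recordings.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
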