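Package: sdmkit
Title: Traceable Sensor-Derived Measures from Structured Smartphone and Wearable Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw smartphone and wearable recordings of structured
    clinical tests (six-minute walk, U-turn, static balance, shape drawing,
    pinching, symbol-digit substitution, tapping, and patient-reported
    questionnaires) into standard-named sensor-derived measures (SDMs).
    Recordings are modelled as readings structured in levels with modalities;
    processing runs as a declarative step graph that records a complete data
    trace (a DAG from raw datasets through transforms to measures) and raises
    typed data-quality flags for technical issues (unstable sampling) and
    user behaviours (wrong device orientation, truncated tests) without ever
    deleting data. Includes a canonical JSON reading format, CSV/JSON measure
    export, a seeded synthetic-recording generator with ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
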