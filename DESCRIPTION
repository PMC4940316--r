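Package: peakelm
Title: Time-Domain EEG Peak Detection with an Extreme Learning Machine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects event-related peaks in single-channel EEG signals by
    screening local maxima as candidate peaks, extracting sixteen time-domain
    features (amplitudes, widths and slopes around each candidate) and
    classifying candidates with a single-hidden-layer extreme learning
    machine trained in closed form by the Moore-Penrose pseudo-inverse.
    Implements four published peak models (Dumpala, Dingle, Acir, Liu) as
    feature subsets and evaluates them under a common protocol with the
    geometric-mean (G_mean) accuracy for imbalanced classes, multi-run
    summaries, and Friedman rank tests with Holm post-hoc comparisons.
    Includes a synthetic generator of annotated EEG-like signals for
    end-to-end testing when no recordings are available.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
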