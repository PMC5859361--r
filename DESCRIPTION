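Package: coolprotocol
Title: Tooling for Individualized, Perception-Based Cooling Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis and simulation tooling for individualized,
    perception-based cold-exposure studies of human thermoregulation and
    brown adipose tissue activity. Provides surface-EMG shiver-event
    detection (zero-phase band-pass and notch filtering, Teager-Kaiser
    energy operator, envelope thresholding with a sliding-window onset
    criterion and gap merging), extraction and matching of self-reported
    shiver intervals from a thermoesthesia slider log, similarity
    fractions between EMG and self-report shiver events, skin-temperature
    vasoconstriction gradients and physiological-marker extraction, a
    deterministic state machine implementing the perception-guided
    cooling protocol, session-log reading, writing and synchronization,
    and a seeded participant simulator that generates complete synthetic
    sessions with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
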