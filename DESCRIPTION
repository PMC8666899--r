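Package: ibidetect
Title: Interbreath Intervals and Central Apnoea Detection from Infant
    Impedance Pneumography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives interbreath intervals (IBIs) and detects central
    apnoeas from the chest impedance pneumograph (IP) of infants.
    Provides artefact masking and cardiac-frequency notch filtering of
    the IP waveform, adaptive-threshold breath detection (threshold a
    multiple of the signal SD over the previous N detected breaths),
    extraction of candidate apnoeas (IBIs of at least 20 s) with linear
    support-vector-machine classification of true apnoeas against
    artefactually low-amplitude signal, bradycardia and desaturation
    co-occurrence utilities, IBI-distribution summaries, and paired
    sign-flip permutation tests with Hochberg correction for
    before/after epoch comparisons. Includes a synthetic-recording
    simulator with exhaustive ground truth so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
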