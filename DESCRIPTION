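Package: apneaband
Title: Sleep-Apnea Event Detection from Multi-Band EEG Energy Ratios
Version: 0.1.0
Authors@R: person("apneaband", "maintainers", email = "maintainers@apneaband.org",
                  role = c("aut", "cre"))
Description: Subject-specific detection of sleep-apnea events from
    two-channel overnight EEG. Frames of the channel-averaged signal are
    decomposed into the five classical EEG frequency bands by FFT-domain
    brick-wall filtering; the inter-band energy ratios (full 10-ratio and
    reduced 5-ratio sets) feed a cosine-distance K-nearest-neighbour
    classifier evaluated by leave-one-out or M-fold cross-validation with
    sensitivity, specificity, accuracy, ROC AUC and the geometrical
    separability index. Includes a minimal EDF reader/writer, a delimited
    text path, a seeded synthetic EEG generator that emulates the apnea
    band-energy shift, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
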