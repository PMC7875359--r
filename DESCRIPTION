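Package: hippoval
Title: Automated Validation Tests for Hippocampal CA1 Pyramidal Cell Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A suite of five automated electrophysiology validation tests for
    single-neuron models of hippocampal CA1 pyramidal cells: somatic features,
    depolarization block, back-propagating action potential, PSP attenuation,
    and oblique dendritic integration.  Tests stimulate a model through a
    standardized capability interface, extract electrophysiological features
    from the recorded voltage traces, and score the model against experimental
    observations via feature-wise Z-scores with test-specific penalty rules.
    Ships with a deterministic phenomenological mock-model backend and a
    synthetic SWC morphology generator so the whole suite runs without a
    biophysical simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
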