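Package: lfpstate
Title: State-Aware Classification and Detection of Sensory-Evoked Cortical LFP Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting and detecting single-trial sensory-evoked
    local field potential (LFP) responses from ongoing cortical activity.
    Pre-stimulus features of the laminar LFP (activation and low-frequency
    power ratio) are mapped by multiclass support-vector classifiers onto a
    quintile-discretized principal-component parameterization of the evoked
    response, and the resulting continuous "cortical state" estimate drives a
    state-aware matched-filter ideal observer that sets detection thresholds
    per state under a fixed overall false-alarm rate. Includes a synthetic
    laminar-probe recording generator with latent state dynamics and full
    ground truth, preprocessing utilities (decimation, line-noise removal,
    channel quality control), one-dimensional kernel current source density,
    and functional layer assignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
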