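Package: dualhfo
Title: Interictal HFO Asymmetry Analysis for Dual-Pathology Epilepsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for interictal biomarkers of the
    seizure-generating lesion in dual-pathology epilepsy. Detects
    interictal epileptic spikes, ripples (80-250 Hz) and fast ripples
    (250-500 Hz) in stereotactic EEG (SEEG), computes per-patient
    hippocampo-neocortical asymmetry ratios of event rates, correlates
    the fast-ripple ratio with the seizure-generating lesion, predicts
    the primary focus by ranking patients on the fast-ripple ratio, and
    assesses prediction accuracy with a multiset-label permutation test
    backed by an exact enumeration oracle. Includes a synthetic SEEG
    cohort generator with known ground truth for end-to-end validation,
    and minimal EDF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
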