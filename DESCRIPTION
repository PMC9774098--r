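Package: sozloc
Title: Seizure Onset Zone Localization from Interictal Stereo-EEG Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Localizes the seizure onset zone (SOZ) at the electrode-contact
    level from interictal stereo-EEG. Detects epileptogenic biomarkers
    (interictal spikes, ripples, fast ripples and co-occurring ripple/fast-
    ripple events) with a Hilbert-envelope detector whose baseline is
    estimated from Stockwell-transform energy entropy, aggregates them into a
    per-contact feature table including a regionally normalized pathological
    ripple rate, selects relevant features with tree-SHAP importances, shadow
    features and binomial hypothesis testing, classifies SOZ versus non-SOZ
    contacts with an attention multilayer perceptron trained with focal loss
    under leave-one-patient-out cross-validation, and renders predicted
    contact scores as a voxel probability map. Includes a synthetic SEEG
    generator so the whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    xgboost,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
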