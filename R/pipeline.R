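#' Extract the full contact feature table from one recording
#'
#' Runs spike detection (every registered detector, or the given ids), HFO
#' detection in both bands with co-occurrence pairing, and assembles the
#' per-contact feature table.
#'
#' @param recording a [seeg_recording()] (bipolar for clinical data;
#'   synthetic recordings are reference-free and used as-is).
#' @param contacts contact metadata table.
#' @param detectors spike detector ids to run.
#' @param ... passed to [build_feature_table()].
#' @return The feature table (see [build_feature_table()]).
#' @export
extract_contact_features <- function(recording, contacts,
                                     detectors = "reference", ...) {
  spikes <- do.call(rbind, lapply(detectors, function(d)
    detect_spikes(recording, d)))
  hfo <- detect_hfos(recording)
  build_feature_table(hfo, spikes, contacts, recording, ...)
}

#' End-to-end SOZ localization on a multi-patient cohort
#'
#' For each patient: biomarker detection and feature extraction; then
#' pooled leave-one-patient-out cross-validation with per-fold ShapHT+
#' feature selection and the attention MLP classifier.
#'
#' @param cohort list of per-patient lists with `recording` and `contacts`
#'   (as from [simulate_cohort()]).
#' @param config a [classifier_config()].
#' @param select run ShapHT+ selection inside each fold.
#' @param ... passed to [extract_contact_features()].
#' @return A list: `features` (pooled table), `cv` (a `soz_loocv` object).
#' @export
localize_soz <- function(cohort, config = classifier_config(),
                         select = TRUE, ...) {
  tabs <- lapply(cohort, function(p)
    extract_contact_features(p$recording, p$contacts, ...))
  features <- do.call(rbind, tabs)
  cv <- loocv(features, config, select = select)
  list(features = features, cv = cv)
}
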