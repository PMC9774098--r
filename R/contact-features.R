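#' Regional physiological ripple rates
#'
#' 95th-percentile physiological ripple rates (events/min) per atlas region
#' index, used as the regional constant subtracted during ripple
#' normalization. Defaults cover the regions of the 17-region intracranial
#' atlas convention encountered in the reference cohort: medial/basal
#' temporal (2), superior/middle/orbital frontal (7), middle/inferior
#' temporal (8), anterior/middle cingulate (9).
#'
#' @return Named numeric vector, names are region indices.
#' @export
regional_ripple_rates <- function() {
  c(`2` = 19.5, `7` = 3.5, `8` = 2.7, `9` = 2.0)
}

#' Biomarker event rate of a contact
#'
#' Event count on the contact divided by the recording duration in minutes.
#'
#' @param events data frame with a `contact` column.
#' @param contact contact name.
#' @param duration_min recording duration, minutes.
#' @return Rate in events/min.
#' @export
biomarker_rate <- function(events, contact, duration_min) {
  if (duration_min <= 0) stop("duration must be positive")
  sum(events$contact == contact) / duration_min
}

#' Normalized pathological ripple rate (regional + 10\% threshold)
#'
#' Three steps per contact: (1) subtract the regional physiological ripple
#' rate for the contact's region; (2) clamp negative results to 0; (3) zero
#' contacts whose ripple count falls below the 10th percentile of the
#' per-contact ripple-count distribution over all contacts of the patient
#' (`rule = "quantile"`, the default; ties at the boundary are kept).
#' `rule = "total"` instead zeroes contacts whose count is below 10\% of the
#' patient's total ripple count.
#'
#' Regions missing from `regional_rates` use a constant of 0 with a warning;
#' an `NA` region is an error naming the contact.
#'
#' @param ripple_rates numeric vector of per-contact ripple rates
#'   (events/min).
#' @param ripple_counts integer vector of per-contact ripple counts.
#' @param regions integer vector of region indices per contact.
#' @param regional_rates named vector as from [regional_ripple_rates()].
#' @param rule percentile convention, `"quantile"` or `"total"`.
#' @param percentile lower tail fraction to zero (0.1 for RT+10).
#' @param contacts optional contact names for error messages.
#' @return Numeric vector of normalized rates, all >= 0.
#' @export
normalize_ripple_rate <- function(ripple_rates, ripple_counts, regions,
                                  regional_rates = regional_ripple_rates(),
                                  rule = c("quantile", "total"),
                                  percentile = 0.1, contacts = NULL) {
  rule <- match.arg(rule)
  n <- length(ripple_rates)
  stopifnot(length(ripple_counts) == n, length(regions) == n)
  if (is.null(contacts)) contacts <- paste0("contact ", seq_len(n))
  if (anyNA(regions)) {
    bad <- which(is.na(regions))[1L]
    stop("region is missing for ", contacts[bad])
  }
  reg_const <- regional_rates[as.character(regions)]
  if (anyNA(reg_const)) {
    missing_regions <- unique(regions[is.na(reg_const)])
    warning("no regional ripple rate for region(s) ",
            paste(missing_regions, collapse = ", "),
            "; using 0 for those contacts")
    reg_const[is.na(reg_const)] <- 0
  }
  r <- ripple_rates - as.numeric(reg_const)
  r[r < 0] <- 0
  cutoff <- if (rule == "quantile")
    as.numeric(stats::quantile(ripple_counts, percentile, type = 7)) else
      percentile * sum(ripple_counts)
  r[ripple_counts < cutoff] <- 0
  r
}

#' Median per-event energy features of a contact
#'
#' For each feature name, the median over all events of the given kind on
#' the contact. Contacts with no events return `NA` per feature (imputed at
#' table level).
#'
#' @param feature_rows data frame: one row per event, columns `contact` plus
#'   feature values.
#' @param contact contact name.
#' @return Named numeric vector of medians (NA when the contact has no
#'   events).
#' @export
median_energy_features <- function(feature_rows, contact) {
  feat_cols <- setdiff(names(feature_rows), c("contact", "kind"))
  rows <- feature_rows[feature_rows$contact == contact, feat_cols, drop = FALSE]
  if (nrow(rows) == 0L)
    return(stats::setNames(rep(NA_real_, length(feat_cols)), feat_cols))
  vapply(rows, stats::median, numeric(1))
}

# events of one kind -> per-event feature rows computed on the signal
.event_feature_rows <- function(recording, events, kind, min_window = 0.25) {
  fs <- recording$sampling_rate
  n <- ncol(recording$signal)
  rows <- list()
  for (i in seq_len(nrow(events))) {
    ci <- match(events$contact[i], recording$channel_names)
    if (is.na(ci)) stop("event on unknown contact ", events$contact[i])
    i0 <- round(events$start[i] * fs) + 1L
    i1 <- round(events$end[i] * fs)
    # widen very short events to a minimum analysis window so the wavelet
    # sub-bands retain enough coefficients for the entropy estimators
    need <- round(min_window * fs) - (i1 - i0 + 1L)
    if (need > 0L) {
      i0 <- i0 - need %/% 2L
      i1 <- i1 + (need - need %/% 2L)
    }
    i0 <- max(1L, i0); i1 <- min(n, i1)
    seg <- recording$signal[ci, i0:i1]
    v <- event_feature_vector(seg, fs, kind)
    rows[[i]] <- c(list(contact = events$contact[i]), as.list(v))
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Build the per-contact feature table
#'
#' Assembles one row per contact: spike rate per detector, ripple rate,
#' normalized pathological ripple rate (RT+10), fast-ripple rate, R&FR rate,
#' and the median event-energy features per biomarker kind. Rate features of
#' event-free contacts are exactly 0; energy features of event-free contacts
#' are imputed with the per-patient column median (the imputation mask is
#' kept in the `imputed` attribute).
#'
#' @param hfo_events data frame from [detect_hfos()].
#' @param spike_events data frame from [detect_spikes()] (possibly several
#'   detectors concatenated).
#' @param contacts contact metadata table (columns `contact`, `patient_id`,
#'   `region`, optionally `soz_label`).
#' @param recording the bipolar [seeg_recording()] the events came from.
#' @param duration_min analysis duration, minutes; defaults to the recording
#'   length.
#' @param spike_segment_s spike segment length, seconds.
#' @param regional_rates regional ripple-rate table.
#' @param normalize_rule RT+10 percentile convention; see
#'   [normalize_ripple_rate()].
#' @return Data frame, one row per contact, with attribute `manifest` (the
#'   feature column names) and `imputed`.
#' @export
build_feature_table <- function(hfo_events, spike_events, contacts, recording,
                                duration_min = NULL, spike_segment_s = 5,
                                regional_rates = regional_ripple_rates(),
                                normalize_rule = "quantile") {
  unknown <- setdiff(unique(c(hfo_events$contact, spike_events$contact)),
                     contacts$contact)
  if (length(unknown) > 0L)
    stop("events reference contacts absent from the contact table: ",
         paste(unknown, collapse = ", "))
  if (is.null(duration_min))
    duration_min <- ncol(recording$signal) / recording$sampling_rate / 60
  cts <- contacts$contact
  n <- length(cts)

  detectors <- unique(spike_events$detector_id)
  if (length(detectors) == 0L) detectors <- "reference"
  out <- data.frame(contact = cts, patient_id = contacts$patient_id,
                    region = contacts$region, stringsAsFactors = FALSE)
  for (d in detectors) {
    sd_ev <- spike_events[spike_events$detector_id == d, , drop = FALSE]
    out[[paste0("srate_", d)]] <-
      vapply(cts, function(ct) biomarker_rate(sd_ev, ct, duration_min), 0)
  }
  rip <- hfo_events[hfo_events$band == "ripple", , drop = FALSE]
  fr <- hfo_events[hfo_events$band == "fast_ripple", , drop = FALSE]
  rfr <- hfo_events[hfo_events$band == "r_and_fr", , drop = FALSE]
  out$r_rate <- vapply(cts, function(ct) biomarker_rate(rip, ct, duration_min), 0)
  counts <- vapply(cts, function(ct) sum(rip$contact == ct), 0)
  out$r_normal_r <- normalize_ripple_rate(out$r_rate, counts, contacts$region,
                                          regional_rates, normalize_rule,
                                          contacts = cts)
  out$fr_rate <- vapply(cts, function(ct) biomarker_rate(fr, ct, duration_min), 0)
  out$rfr_rate <- vapply(cts, function(ct) biomarker_rate(rfr, ct, duration_min), 0)

  # median energy features per biomarker kind
  energy_blocks <- list()
  kinds <- list(
    spike = list(events = NULL, prefix = "spike"),
    ripple = list(events = rip, prefix = "ripple"),
    fast_ripple = list(events = fr, prefix = "fr"),
    r_and_fr = list(events = rfr, prefix = "rfr"))
  # spikes: 5 s segments around the first detector's peaks
  spk <- spike_events[spike_events$detector_id == detectors[1L], , drop = FALSE]
  if (nrow(spk) > 0L) {
    half <- spike_segment_s / 2
    kinds$spike$events <- data.frame(contact = spk$contact,
                                     start = pmax(0, spk$peak_time - half),
                                     end = spk$peak_time + half,
                                     stringsAsFactors = FALSE)
  } else {
    kinds$spike$events <- data.frame(contact = character(0), start = numeric(0),
                                     end = numeric(0), stringsAsFactors = FALSE)
  }
  for (k in names(kinds)) {
    ev <- kinds[[k]]$events
    fm <- feature_manifest(k)
    if (nrow(ev) > 0L) {
      fr_rows <- .event_feature_rows(recording, ev, k)
      med <- t(vapply(cts, function(ct) median_energy_features(fr_rows, ct),
                      numeric(length(fm))))
    } else {
      med <- matrix(NA_real_, n, length(fm), dimnames = list(cts, fm))
    }
    colnames(med) <- paste(kinds[[k]]$prefix, fm, sep = "_")
    energy_blocks[[k]] <- med
  }
  energy <- do.call(cbind, energy_blocks)
  rownames(energy) <- NULL

  # per-patient median imputation for event-free contacts
  imputed <- is.na(energy)
  for (p in unique(out$patient_id)) {
    rows <- out$patient_id == p
    for (j in seq_len(ncol(energy))) {
      nas <- rows & is.na(energy[, j])
      if (any(nas)) {
        med <- stats::median(energy[rows, j], na.rm = TRUE)
        energy[nas, j] <- if (is.finite(med)) med else 0
      }
    }
  }
  out <- cbind(out, as.data.frame(energy))
  if ("soz_label" %in% names(contacts)) out$label <- contacts$soz_label
  attr(out, "manifest") <- setdiff(names(out),
                                   c("contact", "patient_id", "region", "label"))
  attr(out, "imputed") <- imputed
  out
}
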