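# registry of spike detectors; "reference" is installed at load time
.spike_registry <- new.env(parent = emptyenv())

#' Register a spike detector
#'
#' A detector is a function `f(recording, ...)` returning a data frame with
#' columns `contact`, `peak_time` (seconds) and `detector_id`. Registering
#' several detectors yields one spike-rate column per detector in the contact
#' feature table, mirroring clinical practice of running multiple spike
#' detection models side by side.
#'
#' @param detector_id label for the detector.
#' @param fn detector function.
#' @export
register_spike_detector <- function(detector_id, fn) {
  stopifnot(is.character(detector_id), length(detector_id) == 1L, is.function(fn))
  assign(detector_id, fn, envir = .spike_registry)
  invisible(detector_id)
}

#' @rdname register_spike_detector
#' @return `registered_spike_detectors()` returns the registered ids.
#' @export
registered_spike_detectors <- function() {
  sort(ls(.spike_registry))
}

#' Run a registered spike detector
#'
#' @param recording a [seeg_recording()].
#' @param detector_id a registered detector id (see
#'   [registered_spike_detectors()]).
#' @param ... passed to the detector.
#' @return Data frame `contact`, `peak_time`, `detector_id`.
#' @export
detect_spikes <- function(recording, detector_id = "reference", ...) {
  if (!exists(detector_id, envir = .spike_registry, inherits = FALSE))
    stop("unknown spike detector: '", detector_id, "'")
  fn <- get(detector_id, envir = .spike_registry, inherits = FALSE)
  out <- fn(recording, ...)
  if (nrow(out) > 0L) out$detector_id <- detector_id
  out
}

#' Reference interictal spike detector
#'
#' Transparent amplitude/slope detector: a sample is a spike peak when the
#' robust amplitude z-score (relative to the channel median and MAD of the
#' lightly smoothed signal) and the rectified-slope z-score both exceed their
#' thresholds, and the half-amplitude width of the transient lies within the
#' width constraint. Peaks closer than `refractory` seconds keep only the
#' largest. Detection is deterministic and invariant to a DC offset.
#'
#' @param recording a [seeg_recording()].
#' @param amp_z amplitude z-score threshold.
#' @param slope_z slope z-score threshold.
#' @param width_range accepted half-amplitude width, seconds.
#' @param refractory minimum peak separation, seconds.
#' @return Data frame `contact`, `peak_time`, `detector_id`.
#' @export
detect_spikes_reference <- function(recording, amp_z = 5, slope_z = 5,
                                    width_range = c(0.02, 0.07),
                                    refractory = 0.25) {
  stopifnot(inherits(recording, "seeg_recording"))
  fs <- recording$sampling_rate
  out <- list()
  for (ci in seq_along(recording$channel_names)) {
    x <- recording$signal[ci, ]
    xs <- .moving_average(x, max(1L, round(0.005 * fs)))  # 5 ms smoothing
    med <- stats::median(xs)
    s <- stats::mad(xs)
    if (s <= 0) next
    z <- (xs - med) / s
    sl <- c(0, abs(diff(xs)))
    zsl <- sl / stats::mad(sl)
    cand <- which(abs(z) >= amp_z)
    if (length(cand) == 0L) next
    # group candidate samples into transients
    grp <- cumsum(c(1L, diff(cand) > round(0.02 * fs)))
    half_max_ok <- function(pk) {
      thr <- abs(z[pk]) / 2
      i0 <- pk; while (i0 > 1L && abs(z[i0 - 1L]) >= thr) i0 <- i0 - 1L
      i1 <- pk; while (i1 < length(z) && abs(z[i1 + 1L]) >= thr) i1 <- i1 + 1L
      w <- (i1 - i0 + 1L) / fs
      w >= width_range[1L] && w <= width_range[2L]
    }
    peaks <- integer(0)
    for (g in unique(grp)) {
      idx <- cand[grp == g]
      pk <- idx[which.max(abs(z[idx]))]
      win <- max(1L, pk - round(0.035 * fs)):min(length(z), pk + round(0.035 * fs))
      if (max(zsl[win]) < slope_z) next
      if (!half_max_ok(pk)) next
      peaks <- c(peaks, pk)
    }
    if (length(peaks) == 0L) next
    # refractory: keep the larger of any pair closer than `refractory`
    peaks <- peaks[order(-abs(z[peaks]))]
    kept <- integer(0)
    for (pk in peaks)
      if (all(abs(pk - kept) >= refractory * fs)) kept <- c(kept, pk)
    kept <- sort(kept)
    out[[length(out) + 1L]] <- data.frame(
      contact = recording$channel_names[ci],
      peak_time = (kept - 1L) / fs,
      detector_id = "reference", stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(contact = character(0), peak_time = numeric(0),
                      detector_id = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract a fixed-length segment around a spike peak
#'
#' Returns exactly `length_s` seconds of signal centered on `peak_time`,
#' zero-padded where the window extends beyond the recording.
#'
#' @param recording a [seeg_recording()].
#' @param contact channel name.
#' @param peak_time seconds from recording start.
#' @param length_s segment length, seconds (spike segments are 5 s).
#' @return Numeric vector of `round(length_s * fs)` samples.
#' @export
extract_segment <- function(recording, contact, peak_time, length_s = 5) {
  ci <- match(contact, recording$channel_names)
  if (is.na(ci)) stop("unknown contact: '", contact, "'")
  fs <- recording$sampling_rate
  n <- ncol(recording$signal)
  if (peak_time < 0 || peak_time > n / fs)
    stop("peak_time outside the recording")
  len <- round(length_s * fs)
  center <- round(peak_time * fs) + 1L
  i0 <- center - len %/% 2
  idx <- i0:(i0 + len - 1L)
  seg <- numeric(len)
  ok <- idx >= 1L & idx <= n
  seg[ok] <- recording$signal[ci, idx[ok]]
  seg
}
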