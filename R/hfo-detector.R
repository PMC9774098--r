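#' Detector parameters for one HFO band
#'
#' Defaults follow the preliminary-screening algorithm: envelope amplitude cap
#' 30 (ripple) / 20 (fast ripple) microvolts, at least 6 oscillations per
#' event, 10 ms merge gap, baseline windows of fs/100 samples qualified by
#' Stockwell-entropy >= `entropy_fraction` of its maximum and |filtered| <=
#' `baseline_filt_cap` microvolts, envelope threshold at the 95th percentile
#' of baseline envelope samples and oscillation threshold at the 99th
#' percentile of baseline |filtered| samples, candidate windows of 0.02*fs
#' samples above `env_factor * thr`.
#'
#' @param band `"ripple"` (80-250 Hz) or `"fast_ripple"` (250-500 Hz).
#' @param low,high band edges, Hz (defaulted from `band`).
#' @param amplitude_cap envelope rejection cap, microvolts.
#' @param min_oscillations minimum threshold crossings per accepted event.
#' @param merge_gap events closer than this (seconds) are merged.
#' @param baseline_window baseline window length, seconds (fs/100 rule).
#' @param event_window minimum above-threshold run, seconds.
#' @param entropy_fraction fraction of maximum entropy a baseline window must
#'   stay above.
#' @param baseline_env_percentile,baseline_filt_percentile baseline empirical
#'   CDF percentiles defining `thr` and `thr_filt`.
#' @param env_factor candidate threshold is `env_factor * thr`.
#' @param baseline_filt_cap baseline amplitude cap on |filtered|, microvolts.
#' @param st_low,st_high Stockwell band for the entropy criterion, Hz.
#' @param smooth_window envelope moving-average width, seconds.
#' @param edge_guard seconds excluded from event candidacy at each end of
#'   the recording (zero-phase filtering transients).
#' @return An object of class `hfo_params`.
#' @export
hfo_params <- function(band = c("ripple", "fast_ripple"),
                       low = NULL, high = NULL, amplitude_cap = NULL,
                       min_oscillations = 6L, merge_gap = 0.010,
                       baseline_window = 1 / 100, event_window = NULL,
                       entropy_fraction = 0.9,
                       baseline_env_percentile = 95,
                       baseline_filt_percentile = 99,
                       env_factor = 0.99, baseline_filt_cap = 10,
                       st_low = 81, st_high = 500, smooth_window = 0.010,
                       edge_guard = 0.25) {
  band <- match.arg(band)
  if (is.null(low)) low <- if (band == "ripple") 80 else 250
  if (is.null(high)) high <- if (band == "ripple") 250 else 500
  if (is.null(amplitude_cap)) amplitude_cap <- if (band == "ripple") 30 else 20
  # the minimum event duration must be able to contain min_oscillations
  # cycles at the band's upper edge: 20 ms fits 6 cycles at 80-250 Hz
  # (6/250 = 24 ms with envelope taper), but a 6-cycle burst at 400-500 Hz
  # lasts only 12-15 ms, so the fast-ripple window is shorter
  if (is.null(event_window))
    event_window <- if (band == "ripple") 0.020 else 0.010
  if (env_factor <= 0 || env_factor > 1) stop("env_factor must be in (0, 1]")
  if (baseline_env_percentile <= 0 || baseline_env_percentile >= 100 ||
      baseline_filt_percentile <= 0 || baseline_filt_percentile >= 100)
    stop("percentiles must be in (0, 100)")
  if (min_oscillations < 1) stop("min_oscillations must be >= 1")
  if (low >= high) stop("band low edge must be below the high edge")
  structure(as.list(environment()), class = "hfo_params")
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR applied forward and backward (`signal::filtfilt`), so
#' the pass band has no phase distortion; the filter order is chosen so that
#' attenuation one octave outside the band exceeds 40 dB.
#'
#' @param x numeric signal vector.
#' @param sampling_rate Hz.
#' @param low,high band edges, Hz; must satisfy `0 < low < high < fs/2`.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, sampling_rate, low, high) {
  if (low <= 0 || high <= low || high >= sampling_rate / 2)
    stop("band [", low, ", ", high, "] Hz is infeasible at ", sampling_rate, " Hz")
  # Hamming FIR transition width ~ 3.3 fs / order; keep transitions narrow
  # (<= 50 Hz) so bursts near the band edges are not attenuated, and never
  # wider than one octave below `low` (the 40 dB stop-band contract)
  order <- ceiling(3.3 * sampling_rate / min(low / 2, 50))
  order <- min(max(order, 64L), floor((length(x) - 1) / 3))
  if (order %% 2L == 1L) order <- order + 1L
  h <- as.numeric(signal::fir1(order, c(low, high) / (sampling_rate / 2),
                               type = "pass"))
  as.numeric(signal::filtfilt(h, 1, x))
}

# analytic signal magnitude via FFT
.hilbert_env <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1L] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * w, inverse = TRUE) / n)
}

# centered moving average, edge-padded by replication
.moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  xp <- c(rep(x[1L], k), x, rep(x[n], k))
  cs <- cumsum(xp)
  half <- k %/% 2
  lo <- seq_len(n) + k - half
  (cs[lo + k] - cs[lo]) / k
}

#' Smoothed Hilbert envelope of a band-passed signal
#'
#' Magnitude of the analytic signal, smoothed with a moving average
#' (default 10 ms).
#'
#' @param filtered_signal band-passed signal vector.
#' @param sampling_rate Hz.
#' @param smooth_window smoothing width, seconds.
#' @return Non-negative envelope, same length as the input.
#' @export
smoothed_hilbert_envelope <- function(filtered_signal, sampling_rate,
                                      smooth_window = 0.010) {
  if (any(!is.finite(filtered_signal))) stop("filtered signal must be finite")
  env <- .hilbert_env(filtered_signal)
  pmax(.moving_average(env, max(1L, round(smooth_window * sampling_rate))), 0)
}

#' Per-sample energy entropy of the Stockwell transform
#'
#' Computes the Stockwell transform of the raw signal over `st_low`-`st_high`
#' Hz (at a frequency stride, default 10 Hz, to bound memory) and, at every
#' sample, the Shannon entropy of the relative power distribution across
#' those frequencies. White-noise-like (flat-spectrum) instants give entropy
#' near `log(n_bins)`; instants dominated by one oscillation give low
#' entropy. All-zero instants are assigned the maximum `log(n_bins)` by
#' convention.
#'
#' @param x raw signal vector.
#' @param sampling_rate Hz; must be at least `2 * st_high`.
#' @param st_low,st_high analysis band, Hz.
#' @param freq_stride spacing of analysed frequencies, Hz.
#' @param decimate integer decimation factor for the analysis (default: the
#'   largest factor keeping the decimated rate at `2 * st_high`); the
#'   returned series is expanded back to the input length.
#' @return Numeric entropy series, same length as `x`.
#' @export
stockwell_energy_entropy <- function(x, sampling_rate, st_low = 81,
                                     st_high = 500, freq_stride = 10,
                                     decimate = NULL) {
  if (sampling_rate < 2 * st_high)
    stop("sampling_rate must be at least twice the upper Stockwell frequency")
  n_full <- length(x)
  # analyse on a decimated copy when the rate allows it: the entropy is a
  # window-scale baseline statistic and is insensitive to the stride
  if (is.null(decimate)) decimate <- max(1L, floor(sampling_rate / (2 * st_high)))
  if (decimate > 1L) {
    x <- x[seq(1L, n_full, by = decimate)]
    sampling_rate <- sampling_rate / decimate
  }
  n <- length(x)
  X <- stats::fft(x)
  freqs <- seq(st_low, st_high, by = freq_stride)
  bins <- unique(pmax(1L, round(freqs * n / sampling_rate)))
  # circular index helper for the shifted spectrum
  m <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  pow <- matrix(0, n, length(bins))
  for (j in seq_along(bins)) {
    nb <- bins[j]
    gauss <- exp(-2 * pi^2 * m^2 / nb^2)
    shifted <- X[((seq_len(n) - 1L + nb) %% n) + 1L]
    voice <- stats::fft(shifted * gauss, inverse = TRUE) / n
    pow[, j] <- Mod(voice)^2
  }
  tot <- rowSums(pow)
  ent <- rep(log(length(bins)), n)
  ok <- tot > 0
  p <- pow[ok, , drop = FALSE] / tot[ok]
  pl <- p * log(p)
  pl[p == 0] <- 0
  ent[ok] <- -rowSums(pl)
  if (decimate > 1L) ent <- rep(ent, each = decimate)[seq_len(n_full)]
  ent
}

#' Estimate baseline thresholds from entropy-qualified windows
#'
#' Scans consecutive windows of `baseline_window` seconds (the fs/100 rule);
#' a window qualifies as baseline when its mean Stockwell entropy is at or
#' above `entropy_fraction` times the maximum window entropy and |filtered|
#' stays at or below `baseline_filt_cap` throughout. On a pure-noise
#' recording most windows qualify and `thr` approximates the whole-signal
#' envelope percentile. `thr` is the 95th percentile of the
#' envelope over all qualified samples and `thr_filt` the 99th percentile of
#' |filtered| (empirical CDF percentiles per the parameters).
#'
#' @param filtered_signal band-passed signal.
#' @param envelope its smoothed Hilbert envelope.
#' @param entropy_series Stockwell energy entropy of the raw signal.
#' @param sampling_rate Hz.
#' @param params an [hfo_params()].
#' @return A list of class `hfo_baseline`: `thr`, `thr_filt`,
#'   `baseline_samples`.
#' @export
estimate_baseline <- function(filtered_signal, envelope, entropy_series,
                              sampling_rate, params = hfo_params()) {
  n <- length(filtered_signal)
  if (length(envelope) != n || length(entropy_series) != n)
    stop("signal, envelope and entropy series must share length")
  win <- max(2L, round(params$baseline_window * sampling_rate))
  n_win <- n %/% win
  idx_mat <- matrix(seq_len(n_win * win), nrow = win)
  # the entropy condition is evaluated at window scale (window mean):
  # per-sample entropy of stochastic baseline fluctuates, and requiring the
  # raw per-sample maximum over the whole recording would disqualify almost
  # every genuinely quiet window
  win_ent <- colMeans(matrix(entropy_series[seq_len(n_win * win)], nrow = win))
  ent_thr <- params$entropy_fraction * max(win_ent)
  ok <- vapply(seq_len(n_win), function(w) {
    win_ent[w] >= ent_thr &&
      max(abs(filtered_signal[idx_mat[, w]])) <= params$baseline_filt_cap
  }, logical(1))
  if (!any(ok))
    stop(structure(class = c("sozloc_baseline_not_found", "error", "condition"),
                   list(message = paste0(
                     "no baseline window qualified; relax entropy_fraction or ",
                     "baseline_filt_cap"), call = sys.call(-1))))
  keep <- as.vector(idx_mat[, ok])
  structure(list(
    thr = as.numeric(stats::quantile(envelope[keep],
                                     params$baseline_env_percentile / 100)),
    thr_filt = as.numeric(stats::quantile(abs(filtered_signal[keep]),
                                          params$baseline_filt_percentile / 100)),
    baseline_samples = length(keep)), class = "hfo_baseline")
}

#' Merge events separated by less than a gap
#'
#' Overlapping events or events whose gap is below `merge_gap` are unioned
#' into one, keeping the maximum peak envelope and summing nothing; the
#' oscillation count of a merged event is the maximum of its parts.
#' Idempotent on its own output.
#'
#' @param events data frame with `start`, `end` (seconds) and optionally
#'   `peak_envelope`, `oscillation_count`.
#' @param merge_gap seconds.
#' @return Merged events sorted by start.
#' @export
merge_events <- function(events, merge_gap = 0.010) {
  if (nrow(events) <= 1L) return(events)
  events <- events[order(events$start, events$end), , drop = FALSE]
  out <- events[1L, , drop = FALSE]
  for (i in 2L:nrow(events)) {
    j <- nrow(out)
    if (events$start[i] - out$end[j] < merge_gap) {
      out$end[j] <- max(out$end[j], events$end[i])
      if ("peak_envelope" %in% names(out))
        out$peak_envelope[j] <- max(out$peak_envelope[j], events$peak_envelope[i])
      if ("oscillation_count" %in% names(out))
        out$oscillation_count[j] <- max(out$oscillation_count[j],
                                        events$oscillation_count[i])
    } else {
      out <- rbind(out, events[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Detect band-limited events against baseline thresholds
#'
#' A candidate is a maximal run of samples with envelope >=
#' `env_factor * thr` that lasts at least `event_window` seconds and whose
#' peak envelope stays below `amplitude_cap`. A candidate is accepted when
#' the rectified filtered signal crosses `thr_filt` upward at least
#' `min_oscillations` times within the run. Accepted events closer than
#' `merge_gap` are merged.
#'
#' @param envelope smoothed Hilbert envelope.
#' @param filtered_signal band-passed signal.
#' @param baseline an [estimate_baseline()] result.
#' @param sampling_rate Hz.
#' @param params an [hfo_params()].
#' @return Data frame with `start`, `end` (seconds, 0-based half-open),
#'   `peak_envelope`, `oscillation_count`; empty when nothing is detected.
#' @export
detect_band_events <- function(envelope, filtered_signal, baseline,
                               sampling_rate, params = hfo_params()) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      peak_envelope = numeric(0), oscillation_count = integer(0))
  above <- envelope >= params$env_factor * baseline$thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  min_len <- round(params$event_window * sampling_rate)
  guard <- round(params$edge_guard * sampling_rate)
  n <- length(envelope)
  out <- list()
  rect <- abs(filtered_signal)
  for (k in runs) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 <= guard || i1 > n - guard) next
    if (i1 - i0 + 1L < min_len) next
    if (max(envelope[i0:i1]) >= params$amplitude_cap) next
    over <- rect[i0:i1] > baseline$thr_filt
    n_cross <- sum(diff(over) == 1L) + as.integer(over[1L])
    if (n_cross < params$min_oscillations) next
    out[[length(out) + 1L]] <- data.frame(
      start = (i0 - 1L) / sampling_rate, end = i1 / sampling_rate,
      peak_envelope = max(envelope[i0:i1]), oscillation_count = n_cross)
  }
  if (length(out) == 0L) return(empty)
  merge_events(do.call(rbind, out), params$merge_gap)
}

#' Pair ripple and fast-ripple events into co-occurrences
#'
#' Emits one R&FR event for every ripple whose time span overlaps a
#' fast-ripple event on the same contact; the R&FR span is the union of the
#' two.
#'
#' @param ripple_events,fr_events data frames with `contact`, `start`, `end`.
#' @return Data frame of `r_and_fr` events (`contact`, `band`, `start`,
#'   `end`).
#' @export
pair_cooccurrences <- function(ripple_events, fr_events) {
  out <- list()
  for (ct in intersect(unique(ripple_events$contact), unique(fr_events$contact))) {
    rs <- ripple_events[ripple_events$contact == ct, , drop = FALSE]
    fs_ <- fr_events[fr_events$contact == ct, , drop = FALSE]
    for (i in seq_len(nrow(rs))) {
      ov <- fs_$start < rs$end[i] & fs_$end > rs$start[i]
      if (any(ov)) {
        j <- which(ov)[1L]
        out[[length(out) + 1L]] <- data.frame(
          contact = ct, band = "r_and_fr",
          start = min(rs$start[i], fs_$start[j]),
          end = max(rs$end[i], fs_$end[j]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(contact = character(0), band = character(0),
                      start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Detect HFOs on every contact of a recording
#'
#' Runs the full per-band pipeline per channel: band-pass filtering, smoothed
#' Hilbert envelope, Stockwell-entropy baseline estimation, candidate
#' screening, oscillation counting and merging; then pairs co-occurring
#' ripples and fast ripples. The Stockwell entropy of the raw channel is
#' computed once and shared by both bands.
#'
#' @param recording a [seeg_recording()]; clinical referential recordings
#'   should be converted with [to_bipolar()] first (synthetic recordings are
#'   reference-free and used as-is).
#' @param params_ripple,params_fr per-band [hfo_params()].
#' @param freq_stride Stockwell frequency stride, Hz.
#' @return Data frame with `contact`, `band` (`ripple`, `fast_ripple`,
#'   `r_and_fr`), `start`, `end`, `peak_envelope`, `oscillation_count`
#'   (NA for paired events). Attribute `baselines` holds per-channel/band
#'   thresholds. Baseline failures are re-thrown with the channel name.
#' @export
detect_hfos <- function(recording,
                        params_ripple = hfo_params("ripple"),
                        params_fr = hfo_params("fast_ripple"),
                        freq_stride = 10) {
  stopifnot(inherits(recording, "seeg_recording"))
  fs <- recording$sampling_rate
  res <- list(); baselines <- list()
  for (ci in seq_along(recording$channel_names)) {
    ch <- recording$channel_names[ci]
    x <- recording$signal[ci, ]
    ent <- stockwell_energy_entropy(x, fs, params_ripple$st_low,
                                    params_ripple$st_high, freq_stride)
    for (params in list(params_ripple, params_fr)) {
      filt <- bandpass(x, fs, params$low, params$high)
      env <- smoothed_hilbert_envelope(filt, fs, params$smooth_window)
      bl <- tryCatch(
        estimate_baseline(filt, env, ent, fs, params),
        sozloc_baseline_not_found = function(e)
          stop("channel ", ch, " (", params$band, "): ", conditionMessage(e),
               call. = FALSE))
      baselines[[paste(ch, params$band, sep = "/")]] <- bl
      ev <- detect_band_events(env, filt, bl, fs, params)
      if (nrow(ev) > 0L) {
        ev$contact <- ch
        ev$band <- params$band
        res[[length(res) + 1L]] <- ev[, c("contact", "band", "start", "end",
                                          "peak_envelope", "oscillation_count")]
      }
    }
  }
  events <- if (length(res) > 0L) do.call(rbind, res) else
    data.frame(contact = character(0), band = character(0), start = numeric(0),
               end = numeric(0), peak_envelope = numeric(0),
               oscillation_count = integer(0), stringsAsFactors = FALSE)
  rr <- events[events$band == "ripple", , drop = FALSE]
  ff <- events[events$band == "fast_ripple", , drop = FALSE]
  co <- pair_cooccurrences(rr, ff)
  if (nrow(co) > 0L) {
    co$peak_envelope <- NA_real_
    co$oscillation_count <- NA_integer_
    events <- rbind(events, co[, names(events)])
  }
  events <- events[order(events$contact, events$start), , drop = FALSE]
  rownames(events) <- NULL
  attr(events, "baselines") <- baselines
  events
}
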