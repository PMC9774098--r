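#' Simulation configuration for synthetic SEEG
#'
#' Defines the study conditions the generator emulates: interictal stereo-EEG
#' with 1/f background, SOZ contacts enriched in interictal spikes, ripples
#' (80-250 Hz), fast ripples (250-500 Hz) and co-occurring ripple/fast-ripple
#' events, under the class imbalance typical of clinical cohorts.
#'
#' Event rates are per minute. The power spectral density of the background
#' decays as 1/f^`background_exponent`; the default exponent of 2 matches the
#' steep high-band roll-off of intracranial EEG, and `background_sd` (total
#' broadband standard deviation, microvolts) is chosen so that the ripple-band
#' RMS of the background sits in the low-microvolt range seen on clinical
#' depth contacts. `snr_db` is the power signal-to-noise ratio of an injected
#' burst against the variance of the band-passed background in its own band.
#'
#' @param n_contacts number of contacts.
#' @param soz_fraction fraction of contacts labelled SOZ.
#' @param duration recording length, seconds.
#' @param sampling_rate Hz; must be at least 1000 so the fast-ripple band is
#'   representable.
#' @param background_exponent 1/f slope of the background PSD.
#' @param background_sd broadband background standard deviation, microvolts.
#' @param spike_rate_soz,spike_rate_nsoz spike rates, events/min.
#' @param ripple_rate_soz,ripple_rate_nsoz ripple rates, events/min.
#' @param fr_rate_soz,fr_rate_nsoz fast-ripple rates, events/min.
#' @param cooccur_prob probability that a fast ripple co-occurs with a ripple.
#' @param n_cycles oscillation cycles per injected burst (the detector
#'   requires at least 6).
#' @param snr_db burst power SNR in dB relative to in-band background.
#' @param spike_amplitude spike peak amplitude, microvolts.
#' @param region_assignment integer vector recycled over contacts giving each
#'   contact's atlas region index.
#' @param seed integer seed; all generation is reproducible given the config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_contacts = 10, soz_fraction = 0.3, duration = 60,
                       sampling_rate = 2048, background_exponent = 2,
                       background_sd = 15,
                       spike_rate_soz = 12, spike_rate_nsoz = 2,
                       ripple_rate_soz = 20, ripple_rate_nsoz = 2,
                       fr_rate_soz = 8, fr_rate_nsoz = 0.5,
                       cooccur_prob = 0.5, n_cycles = 8, snr_db = 10,
                       spike_amplitude = 120,
                       region_assignment = c(2L, 7L, 8L, 9L), seed = 1L) {
  rates <- c(spike_rate_soz, spike_rate_nsoz, ripple_rate_soz, ripple_rate_nsoz,
             fr_rate_soz, fr_rate_nsoz)
  if (any(rates < 0)) stop("event rates must be non-negative")
  if (duration <= 0 || sampling_rate <= 0) stop("duration and sampling_rate must be positive")
  if (sampling_rate < 1000)
    stop("sampling_rate must be at least 1000 Hz to represent the 250-500 Hz band")
  if (cooccur_prob < 0 || cooccur_prob > 1) stop("cooccur_prob must be in [0,1]")
  if (soz_fraction < 0 || soz_fraction > 1) stop("soz_fraction must be in [0,1]")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate 1/f background SEEG
#'
#' Draws Gaussian white noise per contact and shapes its spectrum so the PSD
#' decays as 1/f^exponent, then rescales each channel to `background_sd`.
#' `exponent = 0` yields white noise. Deterministic for a fixed seed.
#'
#' @param n_contacts number of channels.
#' @param duration seconds.
#' @param sampling_rate Hz.
#' @param exponent 1/f PSD slope.
#' @param seed integer seed.
#' @param background_sd per-channel standard deviation, microvolts.
#' @return A referential [seeg_recording()] with channels named `A1`, `A2`, ...
#' @export
generate_background <- function(n_contacts, duration, sampling_rate,
                                exponent = 2, seed = 1L, background_sd = 15) {
  if (duration <= 0 || sampling_rate <= 0)
    stop("duration and sampling_rate must be positive")
  n <- round(duration * sampling_rate)
  if (n < 1) stop("duration * sampling_rate must be at least 1")
  set.seed(seed)
  freqs <- c(0, seq_len(n - 1)) * sampling_rate / n
  freqs <- pmin(freqs, sampling_rate - freqs)   # two-sided frequency axis
  shaping <- c(0, 1 / freqs[-1]^(exponent / 2)) # zero out DC
  sig <- matrix(0, n_contacts, n)
  for (ch in seq_len(n_contacts)) {
    w <- stats::rnorm(n)
    x <- Re(stats::fft(stats::fft(w) * shaping, inverse = TRUE)) / n
    sig[ch, ] <- x / stats::sd(x) * background_sd
  }
  seeg_recording(sig, sampling_rate, paste0("A", seq_len(n_contacts)),
                 "referential")
}

# biphasic interictal spike template: sharp half-sine + opposite slow wave
.spike_template <- function(fs, amplitude, sharp_s = 0.07, slow_s = 0.2) {
  n1 <- max(4L, round(sharp_s * fs))
  n2 <- max(4L, round(slow_s * fs))
  sharp <- amplitude * sin(pi * seq_len(n1) / (n1 + 1))
  slow <- -0.35 * amplitude * sin(pi * seq_len(n2) / (n2 + 1))
  c(sharp, slow)
}

# Hann-windowed sinusoidal burst with a given cycle count
.burst_template <- function(fs, freq, n_cycles, amplitude) {
  n <- max(8L, round(n_cycles / freq * fs))
  t <- seq_len(n) / fs
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))
  amplitude * hann * sin(2 * pi * freq * t)
}

# uniform random non-overlapping onsets (samples); error when impossible
.place_onsets <- function(k, len_samp, total_samp, margin_samp) {
  if (k == 0L) return(integer(0))
  slot <- len_samp + margin_samp
  if (k * slot > total_samp - 2L * margin_samp)
    stop("cannot place ", k, " events of ", len_samp,
         " samples in the recording without overlap")
  repeat {
    ons <- sort(sample.int(total_samp - len_samp - margin_samp, k)) + margin_samp
    if (k == 1L || all(diff(ons) >= slot)) return(ons)
  }
}

# in-band RMS of the background, per channel, used to set burst amplitudes
.band_sigma <- function(recording, low, high) {
  apply(recording$signal, 1L, function(x)
    stats::sd(bandpass(x, recording$sampling_rate, low, high)))
}

#' Inject biomarker events into a background recording
#'
#' Spikes are biphasic sharp transients (70 ms half-sine) followed by a slow
#' wave; ripple and fast-ripple events are Hann-windowed sinusoidal bursts
#' with `n_cycles` oscillations at a frequency drawn within the band.
#' Burst amplitude is set per channel from `snr_db` against the in-band
#' background RMS. SOZ contacts (the first `ceiling(soz_fraction*n)` channels
#' unless `soz_contacts` is given) receive events at the SOZ rates. With
#' probability `cooccur_prob` a fast ripple is accompanied by a concentric
#' ripple burst, recorded as an additional `r_and_fr` ground-truth event.
#'
#' @param recording background [seeg_recording()].
#' @param config a [sim_config()]; its sampling rate must match.
#' @param seed integer seed.
#' @param soz_contacts optional character vector of SOZ channel names.
#' @return A list with elements `recording` (events added), `events` (ground
#'   truth sorted by onset: `contact`, `kind`, `onset_s`, `duration_s`,
#'   `frequency_hz`, `amplitude`), and `soz_contacts`.
#' @export
inject_events <- function(recording, config, seed = config$seed,
                          soz_contacts = NULL) {
  stopifnot(inherits(recording, "seeg_recording"), inherits(config, "sim_config"))
  if (recording$sampling_rate != config$sampling_rate)
    stop("recording sampling rate does not match config")
  fs <- recording$sampling_rate
  n_samp <- ncol(recording$signal)
  dur_min <- n_samp / fs / 60
  chans <- recording$channel_names
  if (is.null(soz_contacts)) {
    n_soz <- ceiling(config$soz_fraction * length(chans))
    soz_contacts <- chans[seq_len(n_soz)]
  }
  set.seed(seed)
  amp_scale <- sqrt(2 * 10^(config$snr_db / 10))
  sig_r <- .band_sigma(recording, 80, 250)
  sig_f <- .band_sigma(recording, 250, 500)

  ev <- list()
  add_event <- function(contact, kind, onset_samp, len_samp, freq, amp) {
    ev[[length(ev) + 1L]] <<- data.frame(
      contact = contact, kind = kind, onset_s = (onset_samp - 1L) / fs,
      duration_s = len_samp / fs, frequency_hz = freq, amplitude = amp,
      stringsAsFactors = FALSE)
  }

  for (ci in seq_along(chans)) {
    is_soz <- chans[ci] %in% soz_contacts
    r_spk <- if (is_soz) config$spike_rate_soz else config$spike_rate_nsoz
    r_rip <- if (is_soz) config$ripple_rate_soz else config$ripple_rate_nsoz
    r_fr <- if (is_soz) config$fr_rate_soz else config$fr_rate_nsoz

    # spikes
    n_spk <- stats::rpois(1L, r_spk * dur_min)
    if (n_spk > 0L) {
      tmpl <- .spike_template(fs, config$spike_amplitude)
      ons <- .place_onsets(n_spk, length(tmpl), n_samp, round(0.3 * fs))
      for (o in ons) {
        idx <- o:(o + length(tmpl) - 1L)
        recording$signal[ci, idx] <- recording$signal[ci, idx] + tmpl
        add_event(chans[ci], "spike", o, length(tmpl), 0, config$spike_amplitude)
      }
    }
    # ripples (independent of fast ripples)
    n_rip <- stats::rpois(1L, r_rip * dur_min)
    if (n_rip > 0L) {
      amp <- amp_scale * sig_r[ci]
      len0 <- round(config$n_cycles / 90 * fs)   # longest possible burst
      ons <- .place_onsets(n_rip, len0, n_samp, round(0.3 * fs))
      for (o in ons) {
        f <- stats::runif(1L, 90, 230)
        tmpl <- .burst_template(fs, f, config$n_cycles, amp)
        idx <- o:(o + length(tmpl) - 1L)
        recording$signal[ci, idx] <- recording$signal[ci, idx] + tmpl
        add_event(chans[ci], "ripple", o, length(tmpl), f, amp)
      }
    }
    # fast ripples, optionally with a co-occurring ripple
    n_fr <- stats::rpois(1L, r_fr * dur_min)
    if (n_fr > 0L) {
      amp_f <- amp_scale * sig_f[ci]
      len0 <- round(config$n_cycles / 260 * fs)
      ons <- .place_onsets(n_fr, max(len0, round(config$n_cycles / 90 * fs)),
                           n_samp, round(0.3 * fs))
      for (o in ons) {
        f <- stats::runif(1L, 260, 430)
        tmpl <- .burst_template(fs, f, config$n_cycles, amp_f)
        idx <- o:(o + length(tmpl) - 1L)
        recording$signal[ci, idx] <- recording$signal[ci, idx] + tmpl
        add_event(chans[ci], "fast_ripple", o, length(tmpl), f, amp_f)
        if (stats::runif(1L) < config$cooccur_prob) {
          fr_len <- length(tmpl)
          f2 <- stats::runif(1L, 90, 240)
          tmpl2 <- .burst_template(fs, f2, config$n_cycles, amp_scale * sig_r[ci])
          # center the ripple on the fast ripple so the spans overlap
          o2 <- max(1L, o + round((fr_len - length(tmpl2)) / 2))
          o2 <- min(o2, n_samp - length(tmpl2))
          idx2 <- o2:(o2 + length(tmpl2) - 1L)
          recording$signal[ci, idx2] <- recording$signal[ci, idx2] + tmpl2
          add_event(chans[ci], "ripple", o2, length(tmpl2), f2,
                    amp_scale * sig_r[ci])
          u_on <- min(o, o2); u_end <- max(idx[length(idx)], idx2[length(idx2)])
          add_event(chans[ci], "r_and_fr", u_on, u_end - u_on + 1L, f, amp_f)
        }
      }
    }
  }
  events <- if (length(ev) > 0L) do.call(rbind, ev) else
    data.frame(contact = character(0), kind = character(0), onset_s = numeric(0),
               duration_s = numeric(0), frequency_hz = numeric(0),
               amplitude = numeric(0), stringsAsFactors = FALSE)
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  list(recording = recording, events = events, soz_contacts = soz_contacts)
}

#' Simulate a complete synthetic SEEG recording
#'
#' Convenience wrapper: generates background per [generate_background()],
#' injects events per [inject_events()], and builds the contact metadata
#' table (region assignment recycled from the config, synthetic coordinates
#' on a line per shaft, SOZ labels).
#'
#' @param config a [sim_config()].
#' @return A list with `recording`, `events`, `contacts`.
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bg <- generate_background(config$n_contacts, config$duration,
                            config$sampling_rate, config$background_exponent,
                            config$seed, config$background_sd)
  inj <- inject_events(bg, config, seed = config$seed + 1L)
  chans <- bg$channel_names
  regions <- rep_len(config$region_assignment, length(chans))
  contacts <- data.frame(
    contact = chans, patient_id = "P1", region = regions,
    x = 10 + 3.5 * seq_along(chans), y = 20, z = 30,
    soz_label = as.integer(chans %in% inj$soz_contacts),
    stringsAsFactors = FALSE)
  list(recording = inj$recording, events = inj$events, contacts = contacts)
}

#' Generate a contact-level feature table with planted class structure
#'
#' Informative features are drawn from class-shifted normal distributions
#' (mean shift `effect_size` standard deviations between SOZ and non-SOZ
#' rows); noise features are identically distributed in both classes.
#' Deterministic per seed.
#'
#' @param n_soz,n_nsoz row counts per class.
#' @param n_informative,n_noise feature counts; their sum must be >= 1.
#' @param effect_size class mean shift in SD units.
#' @param seed integer seed.
#' @return A data frame with columns `contact`, `patient_id`, `region`,
#'   `label` (1 = SOZ) and features `inf_1..`, `noise_1..`. Informative
#'   feature names carry the `inf_` prefix.
#' @export
generate_feature_table <- function(n_soz, n_nsoz, n_informative, n_noise,
                                   effect_size = 2, seed = 1L,
                                   n_patients = 10L) {
  if (n_informative + n_noise < 1) stop("need at least one feature")
  if (n_soz < 0 || n_nsoz < 0) stop("row counts must be non-negative")
  set.seed(seed)
  n <- n_soz + n_nsoz
  label <- c(rep(1L, n_soz), rep(0L, n_nsoz))
  X <- matrix(stats::rnorm(n * (n_informative + n_noise)), nrow = n)
  if (n_informative > 0)
    X[label == 1L, seq_len(n_informative)] <-
      X[label == 1L, seq_len(n_informative), drop = FALSE] + effect_size
  colnames(X) <- c(if (n_informative > 0) paste0("inf_", seq_len(n_informative)),
                   if (n_noise > 0) paste0("noise_", seq_len(n_noise)))
  ord <- sample.int(n)   # interleave classes
  X <- X[ord, , drop = FALSE]; label <- label[ord]
  df <- data.frame(
    contact = paste0("C", seq_len(n)),
    patient_id = paste0("P", rep_len(seq_len(n_patients), n)),
    region = rep_len(c(2L, 7L, 8L, 9L), n),
    label = label, stringsAsFactors = FALSE)
  cbind(df, as.data.frame(X))
}

#' Simulate a multi-patient SEEG cohort
#'
#' Generates one synthetic recording per patient with patient-specific seeds
#' and contact counts, for end-to-end pipeline evaluation under
#' leave-one-patient-out cross-validation.
#'
#' @param n_patients number of patients.
#' @param contacts_per_patient contacts per patient (recycled).
#' @param config template [sim_config()]; `n_contacts` and `seed` are
#'   overridden per patient.
#' @return A list of per-patient lists (`recording`, `events`, `contacts`),
#'   with `contacts$patient_id` set to `P1..Pn`.
#' @export
simulate_cohort <- function(n_patients = 10L, contacts_per_patient = 10L,
                            config = sim_config()) {
  cpp <- rep_len(contacts_per_patient, n_patients)
  lapply(seq_len(n_patients), function(p) {
    cfg <- config
    cfg$n_contacts <- cpp[p]
    cfg$seed <- config$seed + 1000L * p
    sim <- simulate_recording(cfg)
    sim$contacts$patient_id <- paste0("P", p)
    sim
  })
}
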