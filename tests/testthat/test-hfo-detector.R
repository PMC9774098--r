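fs <- 2048

test_that("band-pass filter passes the band and rejects outside it", {
  t <- seq_len(2 * fs) / fs
  mid <- 1500:2500
  in_band <- bandpass(sin(2 * pi * 150 * t), fs, 80, 250)
  expect_lt(abs(max(abs(in_band[mid])) - 1), 0.05)
  stop_band <- bandpass(sin(2 * pi * 20 * t), fs, 80, 250)
  expect_lt(max(abs(stop_band[mid])), 0.01)
  mix <- bandpass(sin(2 * pi * 20 * t) + sin(2 * pi * 150 * t), fs, 80, 250)
  expect_gt(stats::cor(mix[mid], sin(2 * pi * 150 * t)[mid]), 0.99)
  expect_error(bandpass(t, fs, 250, 80), "infeasible")
  expect_error(bandpass(t, 800, 250, 500), "infeasible")
})

test_that("smoothed Hilbert envelope tracks amplitude", {
  t <- seq_len(2 * fs) / fs
  tone <- 2.5 * sin(2 * pi * 120 * t)
  env <- smoothed_hilbert_envelope(tone, fs)
  expect_lt(max(abs(env[1500:2500] - 2.5)), 0.1)
  expect_equal(length(env), length(tone))
  expect_equal(smoothed_hilbert_envelope(numeric(100) , fs), numeric(100))
  # amplitude-modulated burst: envelope follows the known modulator
  mod <- 1 + 0.8 * sin(2 * pi * 2 * t)
  env_am <- smoothed_hilbert_envelope(mod * sin(2 * pi * 150 * t), fs)
  expect_lt(max(abs(env_am[1500:2500] - mod[1500:2500]) / mod[1500:2500]), 0.1)
})

test_that("Stockwell energy entropy separates flat from concentrated spectra", {
  set.seed(4)
  wn <- rnorm(3 * fs)
  e_wn <- stockwell_energy_entropy(wn, fs)
  expect_length(e_wn, length(wn))
  nb <- length(seq(81, 500, by = 10))
  expect_gt(mean(e_wn), 0.85 * log(nb))
  tone <- sin(2 * pi * 300 * seq_len(3 * fs) / fs)
  e_tone <- stockwell_energy_entropy(tone, fs)
  expect_lt(max(e_tone), 0.85 * mean(e_wn))
  # all-zero signal takes the maximum-entropy convention
  expect_equal(unique(stockwell_energy_entropy(numeric(fs * 2), fs)), log(nb))
})

test_that("baseline thresholds approximate whole-signal percentiles on noise", {
  ch <- fixture("noise_ch", function() {
    bg <- generate_background(1, 30, fs, exponent = 2, seed = 41)
    x <- bg$signal[1, ]
    filt <- bandpass(x, fs, 80, 250)
    env <- smoothed_hilbert_envelope(filt, fs)
    ent <- stockwell_energy_entropy(x, fs)
    list(x = x, filt = filt, env = env, ent = ent)
  })
  p <- hfo_params("ripple")
  bl <- estimate_baseline(ch$filt, ch$env, ch$ent, fs, p)
  expect_gt(bl$thr, 0)
  expect_gt(bl$thr_filt, 0)
  # most of a pure-noise recording qualifies as baseline
  expect_gt(bl$baseline_samples, 0.5 * length(ch$x))
  expect_lt(abs(bl$thr - stats::quantile(ch$env, 0.95)[[1]]) /
              stats::quantile(ch$env, 0.95)[[1]], 0.1)
})

test_that("a recording saturated with oscillations has no baseline", {
  t <- seq_len(10 * fs) / fs
  tone <- 50 * sin(2 * pi * 150 * t)   # |filtered| far above the 10 uV cap
  filt <- bandpass(tone, fs, 80, 250)
  env <- smoothed_hilbert_envelope(filt, fs)
  ent <- stockwell_energy_entropy(tone, fs)
  expect_error(estimate_baseline(filt, env, ent, fs, hfo_params("ripple")),
               class = "sozloc_baseline_not_found")
})

test_that("an 8-cycle burst is detected and a 4-cycle burst is rejected", {
  # both bursts at 10 dB power SNR (amplitude sqrt(2 * 10) x in-band RMS)
  for (cyc in c(8, 4)) {
    ch <- burst_channel(freq = 120, n_cycles = cyc, amp_mult = sqrt(20),
                        seed = 1)
    p <- hfo_params("ripple")
    filt <- bandpass(ch$x, fs, 80, 250)
    env <- smoothed_hilbert_envelope(filt, fs)
    ent <- stockwell_energy_entropy(ch$x, fs)
    bl <- estimate_baseline(filt, env, ent, fs, p)
    ev <- detect_band_events(env, filt, bl, fs, p)
    hit <- sum(ev$start < ch$end & ev$end > ch$start)
    if (cyc == 8) expect_equal(hit, 1) else expect_equal(hit, 0)
    if (cyc == 8 && hit == 1) {
      i <- which(ev$start < ch$end & ev$end > ch$start)
      expect_gte(ev$oscillation_count[i], 6)
      expect_lt(ev$peak_envelope[i], p$amplitude_cap)
    }
  }
})

test_that("detection is deterministic and covariant under amplitude scaling", {
  ch <- burst_channel(freq = 140, seed = 13)
  p <- hfo_params("ripple")
  run_detect <- function(x, params) {
    filt <- bandpass(x, fs, 80, 250)
    env <- smoothed_hilbert_envelope(filt, fs)
    ent <- stockwell_energy_entropy(x, fs)
    bl <- estimate_baseline(filt, env, ent, fs, params)
    detect_band_events(env, filt, bl, fs, params)
  }
  a <- run_detect(ch$x, p)
  expect_identical(a, run_detect(ch$x, p))
  p_scaled <- p
  p_scaled$amplitude_cap <- p$amplitude_cap * 50
  p_scaled$baseline_filt_cap <- p$baseline_filt_cap * 50
  b <- run_detect(50 * ch$x, p_scaled)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
})

test_that("raising env_factor or min_oscillations never adds events", {
  ch <- burst_channel(freq = 110, seed = 19)
  filt <- bandpass(ch$x, fs, 80, 250)
  env <- smoothed_hilbert_envelope(filt, fs)
  ent <- stockwell_energy_entropy(ch$x, fs)
  base <- hfo_params("ripple")
  bl <- estimate_baseline(filt, env, ent, fs, base)
  counts <- sapply(c(0.8, 0.9, 0.99), function(ef) {
    p <- base; p$env_factor <- ef
    nrow(detect_band_events(env, filt, bl, fs, p))
  })
  expect_true(all(diff(counts) <= 0))
  counts_osc <- sapply(c(4L, 6L, 10L), function(mo) {
    p <- base; p$min_oscillations <- mo
    nrow(detect_band_events(env, filt, bl, fs, p))
  })
  expect_true(all(diff(counts_osc) <= 0))
})

test_that("merging is idempotent and matches a brute-force merger", {
  set.seed(31)
  brute_merge <- function(ev, gap) {
    ev <- ev[order(ev$start), ]
    repeat {
      done <- TRUE
      for (i in seq_len(nrow(ev) - 1)) {
        if (ev$start[i + 1] - ev$end[i] < gap) {
          ev$end[i] <- max(ev$end[i], ev$end[i + 1])
          ev <- ev[-(i + 1), ]
          done <- FALSE
          break
        }
      }
      if (done || nrow(ev) < 2) break
    }
    rownames(ev) <- NULL
    ev
  }
  for (trial in 1:25) {
    s <- sort(runif(12, 0, 2))
    ev <- data.frame(start = s, end = s + runif(12, 0.005, 0.05))
    m1 <- merge_events(ev, 0.010)
    expect_equal(m1[, c("start", "end")],
                 brute_merge(ev, 0.010)[, c("start", "end")])
    expect_equal(merge_events(m1, 0.010), m1)   # idempotent
  }
  # 5 ms gap merges, 50 ms gap does not
  two <- data.frame(start = c(1.000, 1.075), end = c(1.070, 1.140))
  expect_equal(nrow(merge_events(two, 0.010)), 1)
  two$start[2] <- 1.120; two$end[2] <- 1.190
  expect_equal(nrow(merge_events(two, 0.010)), 2)
})

test_that("co-occurrence pairing unions overlapping ripple and FR spans", {
  rr <- data.frame(contact = c("A1", "A1", "A2"), band = "ripple",
                   start = c(1.0, 5.0, 2.0), end = c(1.1, 5.1, 2.1))
  ff <- data.frame(contact = c("A1", "A2"), band = "fast_ripple",
                   start = c(1.05, 7.0), end = c(1.12, 7.05))
  co <- pair_cooccurrences(rr, ff)
  expect_equal(nrow(co), 1)
  expect_equal(co$start, 1.0)
  expect_equal(co$end, 1.12)
  expect_equal(nrow(pair_cooccurrences(rr[0, ], ff)), 0)
})

test_that("simultaneous ripple and fast-ripple bursts yield an R&FR event", {
  bg <- generate_background(1, 20, fs, exponent = 2, seed = 43)
  x <- bg$signal[1, ]
  sig_r <- stats::sd(bandpass(x, fs, 80, 250))
  sig_f <- stats::sd(bandpass(x, fs, 250, 500))
  mk <- function(f, amp, n_cyc = 8) {
    n <- round(n_cyc / f * fs)
    amp * (0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))) *
      sin(2 * pi * f * seq_len(n) / fs)
  }
  o <- 10 * fs
  br <- mk(120, 10 * sig_r); bf <- mk(320, 10 * sig_f)
  x[o:(o + length(br) - 1)] <- x[o:(o + length(br) - 1)] + br
  x[o:(o + length(bf) - 1)] <- x[o:(o + length(bf) - 1)] + bf
  rec <- seeg_recording(matrix(x, 1), fs, "A1")
  det <- detect_hfos(rec)
  win <- c((o - 1) / fs - 0.05, (o - 1 + length(br)) / fs + 0.05)
  for (b in c("ripple", "fast_ripple", "r_and_fr")) {
    d <- det[det$band == b & det$start < win[2] & det$end > win[1], ]
    expect_equal(nrow(d), 1)
  }
})
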