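test_that("background generation is reproducible and respects the PSD slope", {
  a <- generate_background(2, 10, 1024, exponent = 1, seed = 5)
  b <- generate_background(2, 10, 1024, exponent = 1, seed = 5)
  expect_identical(a$signal, b$signal)

  slope_of <- function(x, fs) {
    pg <- Mod(stats::fft(x))^2 / length(x)
    f <- (seq_along(pg) - 1) * fs / length(pg)
    keep <- f >= 1 & f <= 100
    # average the periodogram in log-spaced bins before fitting
    bins <- cut(log(f[keep]), 30)
    lp <- tapply(pg[keep], bins, mean)
    lf <- tapply(log(f[keep]), bins, mean)
    stats::coef(stats::lm(log(lp) ~ lf))[[2]]
  }
  white <- generate_background(1, 60, 1024, exponent = 0, seed = 2)
  expect_lt(abs(slope_of(white$signal[1, ], 1024)), 0.2)
  pink <- generate_background(1, 60, 1024, exponent = 1, seed = 2)
  expect_lt(abs(slope_of(pink$signal[1, ], 1024) + 1), 0.2)
})

test_that("invalid generation arguments are rejected", {
  expect_error(generate_background(1, -5, 1024), "positive")
  expect_error(sim_config(ripple_rate_soz = -1), "non-negative")
  expect_error(sim_config(sampling_rate = 512), "1000")
})

test_that("null injection leaves the recording untouched", {
  cfg <- sim_config(n_contacts = 2, duration = 5, spike_rate_soz = 0,
                    spike_rate_nsoz = 0, ripple_rate_soz = 0,
                    ripple_rate_nsoz = 0, fr_rate_soz = 0, fr_rate_nsoz = 0,
                    seed = 3)
  bg <- generate_background(2, 5, 2048, seed = 3)
  inj <- inject_events(bg, cfg)
  expect_identical(inj$recording$signal, bg$signal)
  expect_identical(nrow(inj$events), 0L)
})

test_that("event counts recover configured rates within Poisson error", {
  cfg <- sim_config(n_contacts = 1, soz_fraction = 1, duration = 60,
                    spike_rate_soz = 0, spike_rate_nsoz = 0,
                    ripple_rate_soz = 10, fr_rate_soz = 0, cooccur_prob = 0,
                    seed = 17)
  sim <- simulate_recording(cfg)
  n_rip <- sum(sim$events$kind == "ripple")
  expect_lt(abs(n_rip - 10), 3 * sqrt(10))
})

test_that("forced co-occurrence overlaps every fast ripple with a ripple", {
  cfg <- sim_config(n_contacts = 2, soz_fraction = 1, duration = 30,
                    spike_rate_soz = 0, ripple_rate_soz = 0, fr_rate_soz = 6,
                    cooccur_prob = 1, seed = 9)
  sim <- simulate_recording(cfg)
  frs <- sim$events[sim$events$kind == "fast_ripple", ]
  rips <- sim$events[sim$events$kind == "ripple", ]
  expect_gt(nrow(frs), 0)
  for (i in seq_len(nrow(frs))) {
    ov <- rips$contact == frs$contact[i] &
      rips$onset_s < frs$onset_s[i] + frs$duration_s[i] &
      rips$onset_s + rips$duration_s > frs$onset_s[i]
    expect_true(any(ov))
  }
  expect_true(all(c("r_and_fr") %in% sim$events$kind))
})

test_that("injected bursts carry at least the configured cycle count", {
  cfg <- sim_config(n_contacts = 1, soz_fraction = 1, duration = 30,
                    spike_rate_soz = 0, ripple_rate_soz = 6, fr_rate_soz = 0,
                    cooccur_prob = 0, n_cycles = 8, seed = 23)
  sim <- simulate_recording(cfg)
  fs <- cfg$sampling_rate
  rips <- sim$events[sim$events$kind == "ripple", ]
  for (i in seq_len(nrow(rips))) {
    i0 <- round(rips$onset_s[i] * fs) + 1
    seg <- sim$recording$signal[1, i0:(i0 + round(rips$duration_s[i] * fs) - 1)]
    bp <- bandpass(rep(seg, 3), fs, 80, 250)  # tile to dodge edge taper
    n <- length(seg)
    zc <- sum(diff(sign(bp[(n + 1):(2 * n)])) != 0) / 2
    expect_gte(zc, cfg$n_cycles - 1)
  }
})

test_that("feature tables plant the promised class structure", {
  ft <- generate_feature_table(n_soz = 120, n_nsoz = 349, n_informative = 5,
                               n_noise = 45, effect_size = 2, seed = 4)
  expect_equal(nrow(ft), 469)
  expect_equal(sum(ft$label), 120)
  feat <- as.matrix(ft[, -(1:4)])
  gaps <- abs(colMeans(feat[ft$label == 1, ]) - colMeans(feat[ft$label == 0, ]))
  expect_setequal(names(sort(gaps, decreasing = TRUE))[1:5],
                  paste0("inf_", 1:5))

  # identical seed, identical table
  expect_identical(ft, generate_feature_table(120, 349, 5, 45, 2, seed = 4))

  # null table: no feature separates the classes beyond chance
  ft0 <- generate_feature_table(200, 200, 5, 45, effect_size = 0, seed = 8)
  pv <- vapply(5:54, function(j)
    stats::t.test(ft0[[j]][ft0$label == 1], ft0[[j]][ft0$label == 0])$p.value,
    numeric(1))
  expect_lt(mean(pv < 0.05), 0.2)
})

test_that("cohort simulation assigns patients and SOZ labels", {
  cfg <- sim_config(n_contacts = 4, duration = 4, spike_rate_soz = 1,
                    ripple_rate_soz = 2, fr_rate_soz = 1, seed = 5)
  co <- simulate_cohort(3, 4, cfg)
  expect_length(co, 3)
  expect_equal(unique(co[[2]]$contacts$patient_id), "P2")
  expect_true(all(vapply(co, function(p) sum(p$contacts$soz_label) >= 1, TRUE)))
})
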