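test_that("biomarker rates are counts per minute", {
  ev <- data.frame(contact = rep("A1", 15))
  expect_equal(biomarker_rate(ev, "A1", 30), 0.5)
  expect_equal(biomarker_rate(ev[0, , drop = FALSE], "A1", 30), 0)
  expect_error(biomarker_rate(ev, "A1", 0), "positive")
  set.seed(8)
  ev2 <- data.frame(contact = sample(paste0("A", 1:5), 60, replace = TRUE))
  for (ct in paste0("A", 1:5)) {
    cnt <- 0
    for (i in seq_len(nrow(ev2))) if (ev2$contact[i] == ct) cnt <- cnt + 1
    expect_equal(biomarker_rate(ev2, ct, 10), cnt / 10)
  }
})

test_that("ripple normalization subtracts the regional constant and clamps", {
  # region 2 at 25/min: 25 - 19.5 = 5.5 when the percentile step is inert
  r <- normalize_ripple_rate(ripple_rates = c(25, 25, 25),
                             ripple_counts = c(100, 100, 100),
                             regions = c(2L, 2L, 2L))
  expect_equal(r, c(5.5, 5.5, 5.5))
  # region 7 at 2/min clamps to zero
  r2 <- normalize_ripple_rate(c(2, 30), c(50, 50), c(7L, 2L))
  expect_equal(r2, c(0, 10.5))
  # 20 contacts with counts 1..20: exactly the two lowest are zeroed
  rates <- rep(30, 20)
  r3 <- normalize_ripple_rate(rates, 1:20, rep(2L, 20))
  expect_equal(which(r3 == 0), c(1L, 2L))
  expect_true(all(r3[3:20] > 0))
})

test_that("unknown regions warn and missing regions error", {
  expect_warning(
    r <- normalize_ripple_rate(c(5, 5), c(10, 10), c(2L, 13L)),
    "region")
  expect_equal(r[2], 5)                      # constant 0 applied
  expect_error(normalize_ripple_rate(5, 10, NA_integer_,
                                     contacts = "A3"), "A3")
})

test_that("normalization matches a brute-force oracle across random tables", {
  brute <- function(rates, counts, regions, reg_rates, q = 0.1) {
    out <- numeric(length(rates))
    for (i in seq_along(rates)) {
      v <- rates[i] - reg_rates[as.character(regions[i])]
      if (is.na(v)) v <- rates[i]
      if (v < 0) v <- 0
      out[i] <- v
    }
    cutoff <- stats::quantile(counts, q, type = 7)
    for (i in seq_along(rates)) if (counts[i] < cutoff) out[i] <- 0
    out
  }
  reg_rates <- regional_ripple_rates()
  for (s in 1:10) {
    set.seed(s)
    n <- 50
    rates <- runif(n, 0, 40)
    counts <- rpois(n, 20)
    regions <- sample(c(2L, 7L, 8L, 9L), n, replace = TRUE)
    expect_equal(normalize_ripple_rate(rates, counts, regions),
                 brute(rates, counts, regions, reg_rates))
  }
})

test_that("the literal total-count rule is available behind a flag", {
  rates <- rep(20, 4)
  counts <- c(1, 2, 3, 100)   # total 106; 10% = 10.6
  r <- normalize_ripple_rate(rates, counts, rep(2L, 4), rule = "total")
  expect_equal(which(r == 0), 1:3)
})

test_that("median energy features aggregate per contact", {
  rows <- data.frame(contact = c("A1", "A1", "A1", "A2"),
                     x = c(1, 5, 100, 7), y = c(2, 2, 2, 9))
  m <- median_energy_features(rows, "A1")
  expect_equal(m, c(x = 5, y = 2))
  expect_equal(median_energy_features(rows, "A2"), c(x = 7, y = 9))
  expect_true(all(is.na(median_energy_features(rows, "A3"))))
  set.seed(9)
  big <- data.frame(contact = "C", matrix(rnorm(50 * 6), 50))
  med <- median_energy_features(big, "C")
  for (j in 2:7)
    expect_equal(med[[j - 1]], sort(big[[j]])[c(25, 26)] |> mean())
})

test_that("rates are additive over concatenated segments", {
  # rate over concatenation equals the duration-weighted mean of segment rates
  ev1 <- data.frame(contact = rep("A1", 6))    # 6 events in 10 min
  ev2 <- data.frame(contact = rep("A1", 9))    # 9 events in 20 min
  pooled <- biomarker_rate(rbind(ev1, ev2), "A1", 30)
  weighted <- (biomarker_rate(ev1, "A1", 10) * 10 +
                 biomarker_rate(ev2, "A1", 20) * 20) / 30
  expect_equal(pooled, weighted)
})

test_that("the feature table assembles rates, energies and labels", {
  sim <- fixture("table_sim", function() {
    cfg <- sim_config(n_contacts = 4, soz_fraction = 0.5, duration = 20,
                      spike_rate_soz = 6, spike_rate_nsoz = 3,
                      ripple_rate_soz = 9, ripple_rate_nsoz = 3,
                      fr_rate_soz = 6, fr_rate_nsoz = 3,
                      cooccur_prob = 0.5, seed = 61)
    sim <- simulate_recording(cfg)
    sim$hfo <- detect_hfos(sim$recording)
    sim$spikes <- detect_spikes(sim$recording)
    sim
  })
  ft <- build_feature_table(sim$hfo, sim$spikes, sim$contacts, sim$recording)
  expect_equal(nrow(ft), 4)
  expect_identical(attr(ft, "manifest"),
                   setdiff(names(ft), c("contact", "patient_id", "region", "label")))
  expect_true(all(c("srate_reference", "r_rate", "r_normal_r", "fr_rate",
                    "rfr_rate", "label") %in% names(ft)))
  expect_true(all(ft$r_normal_r >= 0))
  expect_true(all(is.finite(as.matrix(ft[, attr(ft, "manifest")]))))
  # rates agree with direct counting of the detections
  dur_min <- 20 / 60
  rip <- sim$hfo[sim$hfo$band == "ripple", ]
  for (i in 1:4)
    expect_equal(ft$r_rate[i], sum(rip$contact == ft$contact[i]) / dur_min)

  # events on a contact missing from the table are a schema error
  expect_error(build_feature_table(sim$hfo, sim$spikes,
                                   sim$contacts[-1, ], sim$recording),
               "absent")
})

test_that("a zero-event recording yields zero rates and imputed energies", {
  rec <- generate_background(3, 5, 2048, seed = 62)
  contacts <- data.frame(contact = rec$channel_names, patient_id = "P1",
                         region = 2L, x = 1, y = 2, z = 3, soz_label = 0L)
  empty_hfo <- data.frame(contact = character(0), band = character(0),
                          start = numeric(0), end = numeric(0),
                          peak_envelope = numeric(0),
                          oscillation_count = integer(0))
  empty_sp <- data.frame(contact = character(0), peak_time = numeric(0),
                         detector_id = character(0))
  ft <- build_feature_table(empty_hfo, empty_sp, contacts, rec)
  rate_cols <- c("srate_reference", "r_rate", "r_normal_r", "fr_rate", "rfr_rate")
  expect_true(all(as.matrix(ft[, rate_cols]) == 0))
  energy_cols <- setdiff(attr(ft, "manifest"), rate_cols)
  expect_true(all(as.matrix(ft[, energy_cols]) == 0))
  expect_true(all(attr(ft, "imputed")))
})
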