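test_that("time-domain features follow their definitions", {
  expect_equal(time_features(c(0, 1, 0, 0), 100),
               c(time_energy = 1, time_duration = 0.04))
  expect_equal(time_features(rep(3, 50), 100),
               c(time_energy = 9 * 50, time_duration = 0.5))
  set.seed(1)
  x <- rnorm(200)
  loop_sum <- 0
  for (v in x) loop_sum <- loop_sum + v * v
  expect_equal(time_features(x, 100)[["time_energy"]], loop_sum)
})

test_that("Fourier features respect tone location and scaling laws", {
  fs <- 2048
  t <- seq_len(fs) / fs
  tone <- sin(2 * pi * 150 * t)
  f_arg <- fft_features(tone, fs, peak_frequency_mode = "argmax")
  expect_lt(abs(f_arg[["fft_peak_frequency"]] - 150), fs / length(tone) + 1e-9)

  set.seed(2)
  wn <- rnorm(2^14)
  f_wn <- fft_features(wn, fs)
  nb <- length(wn) %/% 2 + 1
  expect_lt(abs(f_wn[["fft_spectral_entropy"]] - log(nb)) / log(nb), 0.06)

  f1 <- fft_features(wn, fs)
  f2 <- fft_features(2 * wn, fs)
  expect_equal(f2[["fft_power"]], 4 * f1[["fft_power"]])
  expect_equal(f2[["fft_spectral_entropy"]], f1[["fft_spectral_entropy"]])
  expect_equal(f2[["fft_maximum"]], 2 * f1[["fft_maximum"]])
  expect_error(fft_features(1:4, fs), "at least 8")
})

test_that("magnitude-spectrum features are invariant to time reversal", {
  set.seed(3)
  x <- rnorm(512)
  expect_equal(fft_features(rev(x), 1000), fft_features(x, 1000),
               tolerance = 1e-9)
  expect_equal(time_features(rev(x), 1000), time_features(x, 1000))
})

test_that("wavelet features degrade gracefully and match the manifest", {
  set.seed(4)
  x <- rnorm(600)
  v <- dwt_features(x, kind = "ripple")
  expect_true(all(is.finite(v)))
  expect_setequal(names(v),
                  grep("^(a4|d4)_", feature_manifest("ripple"), value = TRUE))

  # fast-ripple kind drops Kraskov and Renyi per sub-band
  v_fr <- dwt_features(x, kind = "fast_ripple")
  expect_equal(length(v) - length(v_fr), 4)
  expect_false(any(grepl("kraskov|renyi", names(v_fr))))

  # short signals reduce the decomposition depth with a warning
  expect_warning(v_short <- dwt_features(rnorm(40), kind = "ripple"),
                 "too short")
  expect_true(all(is.finite(v_short)))

  # constant input stays finite through the decomposition (zero padding puts
  # edge structure into the coefficients); the raw estimators hit their
  # documented degenerate minima
  vc <- dwt_features(rep(2, 600), kind = "spike")
  expect_true(all(is.finite(vc)))
  expect_equal(sozloc:::.pfd(rep(2, 600)), 1)
  expect_equal(sozloc:::.kfd(rep(2, 600)), 1)
  expect_equal(sozloc:::.shannon_sq(numeric(100)), 0)
  expect_equal(sozloc:::.renyi2_sq(rep(0, 100)), 0)
  expect_equal(sozloc:::.perm_entropy(rep(1, 100)), 0)
  expect_equal(sozloc:::.sample_entropy(rep(3, 100)), 0)
  expect_equal(sozloc:::.hfd(rep(1, 100)), 1)
  expect_equal(sozloc:::.svd_entropy(rep(2, 100)), 0)
})

test_that("Higuchi dimension orders noise above a sinusoid", {
  set.seed(5)
  noise <- rnorm(512)
  sine <- sin(2 * pi * 5 * seq_len(512) / 512)
  expect_gt(sozloc:::.hfd(noise), sozloc:::.hfd(sine))
  expect_gt(sozloc:::.hfd(noise), 1.5)
  expect_lt(sozloc:::.hfd(sine), 1.5)
})

test_that("sample and permutation entropy match brute-force oracles", {
  naive_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
    emb <- function(mm) {
      n <- length(x) - mm + 1
      matrix(x[outer(1:n, 0:(mm - 1), "+")], n)
    }
    cnt <- function(E) {
      n <- nrow(E); s <- 0
      for (i in 1:(n - 1)) for (j in (i + 1):n)
        if (max(abs(E[i, ] - E[j, ])) <= r) s <- s + 1
      s
    }
    B <- cnt(emb(m)); A <- cnt(emb(m + 1))
    if (A == 0 || B == 0) return(0)
    -log(A / B)
  }
  naive_perm <- function(x, ord = 3) {
    n <- length(x) - ord + 1
    pat <- apply(matrix(x[outer(1:n, 0:(ord - 1), "+")], n), 1,
                 function(v) paste(order(v), collapse = ""))
    p <- table(pat) / n
    -sum(p * log(p))
  }
  set.seed(6)
  for (trial in 1:5) {
    x <- rnorm(90)
    expect_equal(sozloc:::.sample_entropy(x), naive_sampen(x))
    expect_equal(sozloc:::.perm_entropy(x), naive_perm(x))
  }
})

test_that("the feature registry is total per event kind", {
  fs <- 2048
  set.seed(7)
  x <- rnorm(1024)
  for (kind in c("spike", "ripple", "fast_ripple", "r_and_fr")) {
    v <- event_feature_vector(x, fs, kind)
    expect_identical(names(v), feature_manifest(kind))
    expect_false(anyDuplicated(names(v)) > 0)
    expect_true(all(is.finite(v)))
  }
  expect_equal(length(feature_manifest("ripple")) -
                 length(feature_manifest("fast_ripple")), 4)
})
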