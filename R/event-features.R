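# db4 (Daubechies, 4 vanishing moments) analysis low-pass filter,
# cross-checked against PyWavelets during development
.db4_dec_lo <- c(-0.010597401784997278, 0.032883011666982945,
                 0.030841381835986965, -0.187034811718881140,
                 -0.027983769416983850, 0.630880767929590400,
                 0.714846570552541500, 0.230377813308855230)

.db4_dec_hi <- {
  L <- length(.db4_dec_lo)
  rev(.db4_dec_lo) * (-1)^(seq_len(L) - 1L)
}

# one analysis step: full zero-padded convolution, downsample by 2
# (direct time-domain filtering: the filter is 8 taps, FFT padding is slower)
.dwt_step <- function(x, h) {
  L <- length(h)
  z <- c(rep(0, L - 1L), x, rep(0, L - 1L))
  y <- stats::filter(z, h, method = "convolution", sides = 1L)
  y <- y[L:(length(x) + 2L * (L - 1L))]
  y[seq(2L, length(y), by = 2L)]
}

#' Discrete wavelet decomposition (db4 analysis filter bank)
#'
#' Multi-level pyramid decomposition with the Daubechies-4 filters and zero
#' padding. Returns the approximation at the deepest level plus the detail
#' coefficients of every level.
#'
#' @param x numeric signal.
#' @param levels decomposition depth.
#' @return Named list `d1..dL`, `aL` of coefficient vectors.
#' @export
dwt_db4 <- function(x, levels = 4L) {
  out <- list()
  a <- x
  for (l in seq_len(levels)) {
    out[[paste0("d", l)]] <- .dwt_step(a, .db4_dec_hi)
    a <- .dwt_step(a, .db4_dec_lo)
  }
  out[[paste0("a", levels)]] <- a
  out
}

# ---- scalar signal descriptors -------------------------------------------
# All estimators return finite values on finite input; degenerate inputs
# (constant or all-zero) map to the documented minima (0 for entropies,
# 1 for the fractal dimensions).

.shannon_sq <- function(x) {
  e <- x^2
  tot <- sum(e)
  if (tot <= 0) return(0)
  p <- e / tot
  -sum(ifelse(p > 0, p * log(p), 0))
}

.renyi2_sq <- function(x) {
  e <- x^2
  tot <- sum(e)
  if (tot <= 0) return(0)
  p <- e / tot
  -log(sum(p^2))
}

.perm_entropy <- function(x, order = 3L, delay = 1L) {
  n <- length(x) - (order - 1L) * delay
  if (n < 2L) return(0)
  idx <- outer(seq_len(n), (0:(order - 1L)) * delay, `+`)
  E <- matrix(x[idx], nrow = n)
  # encode each ordinal pattern as an integer (pairwise-comparison code)
  code <- integer(n)
  b <- 1L
  for (i in seq_len(order - 1L)) for (j in (i + 1L):order) {
    code <- code + b * (E[, i] < E[, j])
    b <- b * 2L
  }
  p <- tabulate(code + 1L, nbins = b)
  p <- p[p > 0] / n
  -sum(p * log(p))
}

.embed_mat <- function(x, m) {
  n <- length(x) - m + 1L
  matrix(x[outer(seq_len(n), 0:(m - 1L), `+`)], nrow = n)
}

# template matches (Chebyshev distance <= r) for embeddings m and m+1 in one
# pass, vectorized over template pairs at each lag
.count_matches_both <- function(x, m, r) {
  n <- length(x)
  B <- 0; A <- 0
  for (lag in seq_len(n - m)) {
    dx <- abs(x[(1L + lag):n] - x[1L:(n - lag)])
    run <- dx
    for (k in seq_len(m - 1L)) {
      len <- length(run) - 1L
      run <- pmax(run[1L:len], dx[(k + 1L):(k + len)])
    }
    B <- B + sum(run <= r)
    if (length(dx) > m) {
      len <- length(run) - 1L
      runA <- pmax(run[1L:len], dx[(m + 1L):(m + len)])
      A <- A + sum(runA <= r)
    }
  }
  c(B = B, A = A)
}

.sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  if (!is.finite(r) || r <= 0 || length(x) <= m + 1L) return(0)
  cnt <- .count_matches_both(x, m, r)
  if (cnt["A"] == 0 || cnt["B"] == 0) return(0)
  -log(cnt[["A"]] / cnt[["B"]])
}

# Kozachenko-Leonenko / KSG nearest-neighbour differential entropy, 1-D
.kraskov_entropy <- function(x, k = 4L) {
  n <- length(x)
  if (n <= k) return(0)
  xs <- sort(x)
  eps <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    d <- sort(abs(xs[lo:hi] - xs[i]))
    d[k + 1L]   # kth neighbour, excluding self
  }, numeric(1))
  eps <- pmax(eps, .Machine$double.eps)
  digamma(n) - digamma(k) + mean(log(2 * eps))
}

.svd_entropy <- function(x, emb = 10L) {
  if (length(x) <= emb) emb <- max(2L, length(x) - 1L)
  E <- .embed_mat(x, emb)
  s <- svd(E, nu = 0L, nv = 0L)$d
  tot <- sum(s)
  if (tot <= 0) return(0)
  p <- s / tot
  -sum(ifelse(p > 0, p * log(p), 0))
}

.pfd <- function(x) {
  n <- length(x)
  dv <- diff(x)
  ndelta <- sum(dv[-length(dv)] * dv[-1L] < 0)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * ndelta)))
}

.kfd <- function(x) {
  n <- length(x) - 1L
  L <- sum(abs(diff(x)))
  if (L <= 0 || n < 2L) return(1)
  d <- max(abs(x - x[1L]))
  if (d <= 0) return(1)
  log10(n) / (log10(n) + log10(d / L))
}

.hfd <- function(x, k_max = 10L) {
  n <- length(x)
  k_max <- min(k_max, n %/% 2L)
  if (k_max < 2L) return(1)
  Lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) { Lm[m] <- 0; next }
      Lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (floor((n - m) / k) * k) / k
    }
    Lk[k] <- mean(Lm)
  }
  if (all(Lk <= 0)) return(1)
  ok <- Lk > 0
  stats::coef(stats::lm(log(Lk[ok]) ~ log(1 / seq_len(k_max)[ok])))[[2L]]
}

# ---- per-domain feature sets ---------------------------------------------

#' Time-domain event features
#'
#' @param event_signal numeric event segment.
#' @param sampling_rate Hz.
#' @return Named vector: `time_energy` (sum of squared samples),
#'   `time_duration` (seconds).
#' @export
time_features <- function(event_signal, sampling_rate) {
  if (length(event_signal) == 0L) stop("empty event signal")
  c(time_energy = sum(event_signal^2),
    time_duration = length(event_signal) / sampling_rate)
}

#' Fourier-domain event features
#'
#' Computed on the one-sided magnitude spectrum: maximum/mean/minimum
#' magnitude, `fft_peak_frequency` (by default the spread max - min of the
#' magnitudes; `peak_frequency_mode = "argmax"` gives the frequency of the
#' largest magnitude in Hz instead), total power, median power spectral
#' density value, Shannon entropy of the normalized PSD, the maximum
#' absolute spectrum value, and the variance of the magnitudes.
#'
#' @param event_signal numeric vector of at least 8 samples.
#' @param sampling_rate Hz.
#' @param peak_frequency_mode `"range"` or `"argmax"`.
#' @return Named numeric vector of 9 features prefixed `fft_`.
#' @export
fft_features <- function(event_signal, sampling_rate,
                         peak_frequency_mode = c("range", "argmax")) {
  peak_frequency_mode <- match.arg(peak_frequency_mode)
  n <- length(event_signal)
  if (n < 8L) stop("fft_features needs at least 8 samples")
  mag <- Mod(stats::fft(event_signal))[seq_len(n %/% 2L + 1L)]
  psd <- mag^2 / (n * sampling_rate)
  tot <- sum(psd)
  if (tot > 0) {
    p <- psd / tot
    spec_ent <- -sum(ifelse(p > 0, p * log(p), 0))
  } else {
    spec_ent <- log(length(psd))   # max-entropy convention for silence
  }
  peak <- if (peak_frequency_mode == "range") max(mag) - min(mag) else
    (which.max(mag) - 1L) * sampling_rate / n
  c(fft_maximum = max(mag),
    fft_mean = mean(mag),
    fft_minimum = min(mag),
    fft_peak_frequency = peak,
    fft_power = sum(mag^2) / n,
    fft_psd = stats::median(psd),
    fft_spectral_entropy = spec_ent,
    fft_spectrum = max(mag),
    fft_variance = stats::var(mag))
}

# per-sub-band DWT feature set; Kraskov and Renyi entropies are omitted for
# the short fast-ripple and R&FR events
.dwt_band_features <- function(coefs, include_kr) {
  f <- c(shannon = .shannon_sq(coefs),
         permutation = .perm_entropy(coefs),
         sampen = .sample_entropy(coefs),
         energy = sum(coefs^2),
         svd = .svd_entropy(coefs),
         pfd = .pfd(coefs),
         kfd = .kfd(coefs),
         hfd = .hfd(coefs))
  if (include_kr)
    f <- c(kraskov = .kraskov_entropy(coefs), renyi = .renyi2_sq(coefs), f)
  f
}

#' Wavelet-domain event features
#'
#' Decomposes the event with [dwt_db4()] and computes, per configured
#' sub-band (default the level-4 approximation `a4` and detail `d4`):
#' Shannon entropy of normalized squared coefficients, Renyi entropy
#' (order 2), permutation entropy (order 3, delay 1), sample entropy
#' (m = 2, r = 0.2 sd), Kozachenko-Leonenko differential entropy (k = 4),
#' energy, SVD entropy (embedding 10), Petrosian, Katz and Higuchi fractal
#' dimensions (k_max = 10). For `kind` `"fast_ripple"` or `"r_and_fr"` the
#' Kraskov and Renyi entropies are omitted (those events are too short for
#' stable estimates).
#'
#' @param event_signal numeric event segment.
#' @param levels decomposition depth; reduced with a warning when the signal
#'   is too short.
#' @param subbands sub-band names to featurize.
#' @param kind event kind (`spike`, `ripple`, `fast_ripple`, `r_and_fr`).
#' @return Named numeric vector, names like `a4_hfd`.
#' @export
dwt_features <- function(event_signal, levels = 4L,
                         subbands = c("a4", "d4"),
                         kind = c("spike", "ripple", "fast_ripple", "r_and_fr")) {
  kind <- match.arg(kind)
  max_lev <- max(1L, floor(log2(length(event_signal) / 8)))
  if (levels > max_lev) {
    warning("signal too short for ", levels, " levels; using ", max_lev)
    levels <- max_lev
    subbands <- unique(sub("[0-9]+$", levels, subbands))
  }
  dec <- dwt_db4(event_signal, levels)
  include_kr <- !(kind %in% c("fast_ripple", "r_and_fr"))
  out <- numeric(0)
  for (sb in subbands) {
    if (is.null(dec[[sb]])) stop("unknown sub-band: ", sb)
    f <- .dwt_band_features(dec[[sb]], include_kr)
    names(f) <- paste(sb, names(f), sep = "_")
    out <- c(out, f)
  }
  out
}

#' Full per-event feature vector
#'
#' Spikes receive wavelet-domain features only; HFO events (ripple,
#' fast ripple, R&FR) receive time-, Fourier- and wavelet-domain features.
#'
#' @param event_signal numeric event segment.
#' @param sampling_rate Hz.
#' @param kind event kind.
#' @param ... passed to [dwt_features()].
#' @return Named numeric vector; all values finite.
#' @export
event_feature_vector <- function(event_signal, sampling_rate,
                                 kind = c("spike", "ripple", "fast_ripple",
                                          "r_and_fr"), ...) {
  kind <- match.arg(kind)
  v <- if (kind == "spike") dwt_features(event_signal, kind = kind, ...) else
    c(time_features(event_signal, sampling_rate),
      fft_features(event_signal, sampling_rate),
      dwt_features(event_signal, kind = kind, ...))
  v[!is.finite(v)] <- 0
  v
}

#' Feature name manifest per event kind
#'
#' Enumerates the exact feature names [event_feature_vector()] produces for
#' each event kind, for schema checks and output provenance.
#'
#' @param kind event kind.
#' @param subbands wavelet sub-bands in use.
#' @return Character vector of feature names.
#' @export
feature_manifest <- function(kind = c("spike", "ripple", "fast_ripple",
                                      "r_and_fr"),
                             subbands = c("a4", "d4")) {
  kind <- match.arg(kind)
  base_dwt <- c("shannon", "permutation", "sampen", "energy", "svd",
                "pfd", "kfd", "hfd")
  if (!(kind %in% c("fast_ripple", "r_and_fr")))
    base_dwt <- c("kraskov", "renyi", base_dwt)
  dwt_names <- as.vector(t(outer(subbands, base_dwt, paste, sep = "_")))
  if (kind == "spike") return(dwt_names)
  c("time_energy", "time_duration",
    paste0("fft_", c("maximum", "mean", "minimum", "peak_frequency", "power",
                     "psd", "spectral_entropy", "spectrum", "variance")),
    dwt_names)
}
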