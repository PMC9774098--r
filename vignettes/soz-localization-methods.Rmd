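---
title: "Localizing the seizure onset zone from interictal SEEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing the seizure onset zone from interictal SEEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sozloc)
```

## The problem

Surgery for drug-resistant focal epilepsy requires localizing the seizure
onset zone (SOZ) — the tissue that generates clinical seizures. Stereo-EEG
(SEEG) depth electrodes record directly from candidate structures, but ictal
recordings are scarce; the interictal record is long and rich, and it carries
quantifiable epileptogenic biomarkers: interictal spikes, ripples (80–250 Hz),
fast ripples (250–500 Hz), and ripples co-occurring with fast ripples (R&FR).
`sozloc` turns a multi-channel interictal recording plus contact metadata into
a per-contact SOZ probability, evaluated under leave-one-patient-out
cross-validation, and renders the scores as a voxel map.

The pipeline has five stages, each exposed as ordinary functions so any stage
can be used alone: biomarker detection (`detect_spikes()`, `detect_hfos()`),
contact-level feature aggregation (`build_feature_table()`), feature selection
(`select_features()`), classification (`soz_net()`, `loocv()`), and voxel
mapping (`scores_to_voxelmap()`).

## HFO detection by envelope screening

For each channel and band the detector band-pass filters the signal
(zero-phase Hamming FIR; transition bands at most 50 Hz so bursts near the
band edges are not attenuated by the filter skirt, and at least 40 dB
attenuation one octave outside the band), computes the Hilbert envelope,
and smooths it with a 10 ms moving average.

**Baseline estimation.** Thresholds must describe event-free background. The
detector computes the Stockwell transform of the raw signal over 81–500 Hz
(at a 10 Hz frequency stride and on a decimated copy when the sampling rate
allows — the entropy is a window-scale statistic and is insensitive to both
choices) and, at each instant, the Shannon entropy of the relative power
across frequencies. Background has a flat in-band spectrum (entropy near the
`log(n bins)` maximum); an oscillatory event concentrates power and pulls the
entropy down. Windows of `fs/100` samples qualify as baseline when their mean
entropy is at least 0.9 of the maximum window entropy and the filtered signal
stays within ±10 µV. The entropy condition is evaluated at window scale
because the per-sample entropy of a stochastic background fluctuates: gating
every sample on the global per-sample maximum (an extreme value) disqualifies
almost every genuinely quiet window and biases both thresholds low. On a
pure-noise recording most windows qualify and the envelope threshold
approximates the whole-signal 95th percentile, which is the behaviour the
procedure intends.

The envelope threshold `thr` is the 95th percentile of the baseline envelope;
the oscillation threshold `thr_filt` is the 99th percentile of the baseline
rectified filtered signal.

**Event candidacy.** A candidate is a maximal run with envelope ≥
`0.99 · thr` lasting at least the event window and peaking below the
amplitude cap (30 µV for ripples, 20 µV for fast ripples — caps exclude
artifacts). The event window is 20 ms in the ripple band; in the fast-ripple
band it is 10 ms, because a 6–8-cycle burst above 400 Hz lasts at most 20 ms
and its supra-threshold envelope run covers only 60–70 % of that — a 20 ms
requirement would categorically reject in-band fast ripples. A candidate is
accepted when the rectified filtered trace crosses `thr_filt` upward at least
6 times within the run (six oscillations), and accepted events closer than
10 ms are merged. The first and last 0.25 s of a recording are excluded from
candidacy (zero-phase filter transients). An R&FR event is emitted whenever a
ripple and a fast-ripple event overlap on the same contact.

**What screening can and cannot do.** These thresholds sit deliberately low —
this is a screening stage. On a synthetic Gaussian 1/f background the
detector fires on noise excursions at roughly 1.5–2.5 events/min per contact
per band; at realistic event rates that bounds event-level precision near
0.8 even when sensitivity exceeds 0.95. Possible remedies (raising the
envelope percentile, demanding more oscillations) would depart from the
procedure's stated operating point, so the package reports the measured
precision rather than tuning the thresholds to the synthetic noise. A
variant that bridges candidate runs across sub-10 ms envelope dips before the
duration test was piloted and rejected: it triples the noise false-positive
rate.

## Spike detection

The package ships one transparent reference detector
(`detect_spikes_reference()`): a peak is a spike when its robust amplitude
z-score (median/MAD of the 5 ms-smoothed trace) and nearby rectified-slope
z-score both exceed 5 and the half-amplitude width lies in 20–70 ms, with a
250 ms refractory rule. Deep-learning detectors trained on clinical archives
can be attached through `register_spike_detector()`; each registered detector
contributes its own spike-rate column to the feature table, so the table
schema supports multiple detection models side by side.

## Contact features

Rates are counts per minute over the analysis duration (clinically 30 min;
the synthetic recordings are shorter and the duration is read from the
recording). The **normalized pathological ripple rate** corrects the raw
ripple rate in three steps: subtract a regional physiological ripple rate
(95th-percentile rates per atlas region: medial/basal temporal 19.5,
frontal 3.5, middle/inferior temporal 2.7, cingulate 2.0 events/min); clamp
negatives to zero; zero every contact whose ripple count falls below the 10th
percentile (type-7 quantile, ties kept) of the per-contact count distribution
for that patient. The percentile is taken over the distribution of
per-contact counts; a literal reading — below 10 % of the patient's total
ripple count — is available via `rule = "total"`. Regions without a published
constant contribute 0 with a warning rather than silently corrupting the
subtraction.

Per-event signal features are computed in three domains and summarized per
contact by the median over events (event-free contacts get 0 for rates,
which is exact, and the per-patient column median for energy features, with
the imputation mask retained):

* time: energy, duration;
* Fourier (one-sided magnitude spectrum): maximum, mean, minimum,
  peak frequency (literally the spread max − min of the magnitudes, with an
  argmax-frequency alternative behind a flag), total power, median PSD,
  spectral entropy, maximum spectrum, variance;
* wavelet (db4, level-4 approximation `a4` and detail `d4`): Shannon, Renyi
  (order 2), permutation (order 3, delay 1), sample (m = 2, r = 0.2 sd),
  Kozachenko–Leonenko (k = 4) entropies, energy, SVD entropy (embedding 10),
  and Petrosian, Katz, Higuchi (k_max = 10) fractal dimensions.

Fast-ripple and R&FR events omit the Kraskov and Renyi entropies: those
events are too short for stable estimates. Spikes carry wavelet features
only, computed on 5 s peak-centered segments; HFO events of unfixed length
are widened to a 0.25 s analysis window so the level-4 sub-bands retain
enough coefficients. Every estimator returns a finite value on finite input;
constant signals map to documented degenerate values (0 for entropies, 1 for
fractal dimensions). The default registry yields 110 feature columns (105
energy features plus 5 rates, one spike-rate column per registered detector);
the exact enumeration is configurable (`feature_manifest()`) since sub-band
conventions vary and published totals depend on them.

## ShapHT+ feature selection

A gradient-boosted tree ensemble (100 trees, depth 3, learning rate 0.1,
class-balanced weighting — the hyperparameter set lists a learning rate, so
boosting is the primary reading and a bagged forest makes no use of it) is
fitted to the feature table. TreeSHAP attributions give per-sample local
importances `|contribution|`; their per-feature mean is the global
importance. Shadow features — permuted copies of real columns, carrying no
label information — calibrate a threshold `Tre = c_l · max(GI_shadow)`, with
`c_l` ramping to 1. Each real feature's hit count (samples with local
importance above `Tre`) is tested against the shadow hit probability with a
one-sided binomial test; Benjamini–Hochberg at α = 0.05 fixes the relevant
set.

Two defaults differ from the obvious minimal choices, for measured reasons:
one shadow is appended per real feature (a handful of shadows makes
`max(GI_shadow)` a weak null envelope — piloting with 5 shadows selected ~16
of 50 pure-noise features), and the binomial null probability is the maximum
per-shadow hit rate, so a feature must beat the luckiest label-free column.
With these defaults the planted-feature recovery stays complete while null
selections fall to ~0.3 per run.

## Classifier: attention MLP with focal loss

The classifier is a four-layer perceptron (features → 128 → 128 → 128 → 2,
ReLU, dropout 0.3 after layers 1 and 3) with an attention block and a softmax
head, trained 20 epochs with batch size 4 and NAdam at learning rate 1e-4 —
implemented in base R with explicit forward/backward passes so every
computation is inspectable and seeded runs are bit-reproducible on one
machine.

Attention follows the standard additive form: `u_t = tanh(W_w e_t + b_w)`,
`h_t = softmax_t(u_t' u_w)`, `v = Σ_t h_t e_t`, so `v` is a convex
combination of the sequence elements and the weights sum to one. Contact
rows have no time axis; the sequence is formed over the hidden-unit axis by
reshaping the 128-unit third-layer activation into 8 segments of 16 units
(both config keys). The insertion point is itself a design choice the source
procedure leaves open.

Focal loss `−α_y (1 − p_true)^γ log p_true` down-weights easy majority
examples; γ = 2 and class weights (0.75, 0.25) are the canonical defaults of
the original focal-loss formulation, configurable because the procedure
states neither. With γ = 0 and α = 1 the loss is exactly cross-entropy (a
unit-tested identity).

**Cross-validation.** Leave-one-patient-out: each fold tests on one patient,
validates on the next patient in rotation (lowest validation focal loss
selects the epoch), and trains on the remainder — testing P1 trains and
validates on P2–P10. Feature selection, standardization and training see
only the fold's training rows, so no test-patient information leaks. Fold
metrics are averaged unweighted across patients.

## Voxel mapping

Contact probabilities are interpolated onto a voxel grid: boundary voxels
(in-mask voxels touching the outside) take the minimum predicted probability;
voxels within 2 voxels of a contact take that contact's probability (nearest
contact wins); all other in-mask voxels are normalized Gaussian-kernel
(σ = 5 mm) convex combinations of the contact values and the boundary value,
so the map cannot overshoot the anchor range. The neighbourhood radius and σ
are defaults of this package — the source procedure quantifies neither. Tests
run on a synthetic ellipsoid mask; MRI co-registration is out of scope.

## The synthetic generator

Because clinical SEEG cannot be redistributed, `sim_config()` +
`simulate_recording()` emulate the statistical structure the pipeline
assumes: 1/f^2 Gaussian background (the steep high-band roll-off of
intracranial EEG) scaled to 15 µV broadband so the ripple-band RMS sits in
the low-microvolt range of clinical depth contacts; biphasic spikes (70 ms
half-sine plus a 200 ms slow wave, 120 µV); Hann-windowed bursts with 8
cycles (the detector needs 6) at 90–230 Hz and 260–430 Hz — away from band
edges, where any band-limited detector is blind by construction; burst
amplitudes set by a 10 dB power SNR against the in-band background RMS;
uniform non-overlapping placement with a 0.3 s margin; SOZ contacts enriched
in all biomarkers (defaults: spikes 12 vs 2, ripples 20 vs 2, fast ripples
8 vs 0.5 events/min; half of fast ripples co-occur with a ripple); and the
~120:349 SOZ:non-SOZ contact imbalance of the reference cohort for tabular
scenarios.

What the generator does **not** emulate: pulse/movement/electrode artifacts,
volume conduction between contacts, non-stationary sleep architecture, ictal
dynamics, and the overlap of physiological with pathological ripple
morphology. Passing tests on this generator therefore demonstrate internal
correctness and the pipeline's behaviour under its own assumptions — not
clinical performance.

## Numerical choices and degenerate inputs

* All time coordinates are seconds from recording start, 0-based; sample
  intervals are half-open.
* EDF signals are 16-bit; the writer chooses per-channel physical ranges, so
  round trips are exact to one quantization step.
* All-zero Stockwell frames take the maximum-entropy convention
  `log(n bins)`; an all-zero spectrum likewise.
* Probabilities at exactly 0/1 are clipped at 1e-12 in the focal loss, with
  a warning.
* Undefined metrics (zero denominators) are reported as missing, never 0,
  and skipped in cross-patient means with a logged count.
* A recording with no qualifying baseline window raises a condition of class
  `sozloc_baseline_not_found` naming the channel, with a hint to relax the
  entropy fraction or amplitude cap.
* Merging is idempotent and order-independent; ties at the RT+10 percentile
  boundary are kept, not zeroed.

## Problem sizes used by the tests

The test suite and the acceptance script run, by design, at desk scale:
detector checks use 10 contacts × 60 s at 2048 Hz; selection checks use
400 × 50 tables over 10 seeds; the end-to-end check uses 10 synthetic
patients × 10 contacts × 60 s with per-fold selection. These sizes were
chosen so the full pipeline exercises every stage in minutes while leaving
the per-stage statistics (Poisson event counts, binomial tests, fold metrics)
interpretable.

## Known limitations

* The envelope screen bounds precision near 0.8 on Gaussian background (see
  above); downstream confirmation models would be needed for higher purity.
* The reference spike detector is a stand-in interface implementation, not a
  validated clinical detector.
* Regional ripple constants cover four atlas regions; others default to 0
  with a warning.
* The classifier is CPU-oriented; it is intentionally small (a few hundred
  contacts per cohort).
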