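# sozloc

Contact-level localization of the seizure onset zone (SOZ) from **interictal
stereo-EEG (SEEG)**, for researchers working on quantitative presurgical
evaluation of drug-resistant focal epilepsy.

Ictal recordings are scarce; the interictal record is long and carries
quantifiable epileptogenic biomarkers. `sozloc` implements the full analysis
chain from raw multichannel signal to a per-contact SOZ probability and a
voxel map:

1. **Biomarker detection** — interictal spikes (pluggable detector registry
   with a transparent amplitude/slope reference detector) and high-frequency
   oscillations: ripples (80–250 Hz), fast ripples (250–500 Hz) and
   co-occurring ripple–fast-ripple events (R&FR). HFOs are screened by a
   Hilbert-envelope detector whose baseline is estimated from
   Stockwell-transform energy entropy: an event is a run with smoothed
   envelope ≥ 0.99·thr (thr = 95th percentile of the baseline envelope),
   peak below an amplitude cap (30/20 µV), at least 6 oscillations (rectified
   crossings of the 99th-percentile baseline threshold), events closer than
   10 ms merged.
2. **Contact features** — per-contact biomarker rates (events/min), including
   a **normalized pathological ripple rate**
   `R_normal = max(R_rate − R_region, 0)`, zeroed for contacts in the lowest
   10 % of per-contact ripple counts (the "regional + 10 %" rule, with
   region-wise physiological rates 19.5 / 3.5 / 2.7 / 2.0 events/min), plus
   median per-event signal features in the time, Fourier and db4-wavelet
   domains (entropies, energies, fractal dimensions).
3. **ShapHT+ feature selection** — TreeSHAP local/global importances from a
   gradient-boosted ensemble (100 trees, depth 3, η = 0.1, class-balanced),
   a shadow-feature threshold `Tre = c_l · max(GI*)`, and per-feature binomial
   hypothesis tests (BH-corrected) splitting features into relevant and
   irrelevant.
4. **Classification** — an attention MLP (`n → 128 → 128 → 128 → 2`, dropout
   0.3, additive attention `u_t = tanh(W_w e_t + b_w)`,
   `h_t = softmax(u_tᵀu_w)`, `v = Σ h_t e_t`) trained with focal loss
   `−α(1−p)^γ log p` and NAdam (lr 1e-4, 20 epochs, batch 4) under
   **leave-one-patient-out cross-validation** (test one patient, validate on
   the next, train on the rest).
5. **Evaluation & mapping** — per-patient sensitivity/specificity/accuracy/
   PPV/NPV averaged across folds, and Gaussian-kernel interpolation of
   contact probabilities onto a brain-masked voxel grid written as NIfTI.

Clinical SEEG cannot be redistributed, so the package includes a synthetic
generator (`sim_config()`, `simulate_recording()`, `simulate_cohort()`)
producing 1/f background, spikes and band-limited bursts with known ground
truth and SOZ-enriched rates; every stage is tested against it. See the
methods vignette (`vignettes/soz-localization-methods.Rmd`) for the models,
assumptions and limitations.

## Worked example

```r
library(sozloc)

# a 10-patient synthetic cohort, 10 contacts each, 60 s at 2048 Hz
cohort <- simulate_cohort(10, 10, sim_config(seed = 42))

# detection -> features -> per-fold ShapHT+ -> attention MLP -> LOOCV
res <- localize_soz(cohort, classifier_config(seed = 7), select = TRUE)
summary(res$cv)
```

```
        SEN SPE ACC PPV    NPV
P1   100.00 100 100 100 100.00
P2   100.00 100 100 100 100.00
P3    66.67 100  90 100  87.50
P4   100.00 100 100 100 100.00
...
Mean  96.67 100  99 100  98.75
```

One patient's fold misses one of its three SOZ contacts (SEN 66.67); averaged
over patients the pipeline recovers SOZ contacts with ~97 % sensitivity and
100 % specificity on its own generator — a statement about internal
correctness under the generator's assumptions, not about clinical data.

Mapping the scores of one patient to a volume:

```r
p1 <- res$cv$predictions[res$cv$predictions$patient_id == "P1", ]
coords <- as.matrix(cohort[[1]]$contacts[, c("x", "y", "z")])
vm <- scores_to_voxelmap(coords, p1$probability, ellipsoid_mask(c(64, 64, 64)))
write_volume(vm, "P1_sozmap.nii.gz")
```

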