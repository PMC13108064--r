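# hrvogtt

Classification of cardiometabolic autonomic phenotypes — metabolic
syndrome (MetS), healthy controls (C) and endurance-trained marathon
runners (M) — from multilead ECG recorded across the five stages of an
oral glucose tolerance test (OGTT; 0/30/60/90/120 min after a 75 g
glucose load).

The package implements the full chain:

1. **Multilead R-peak detection** — a modified Pan–Tompkins cascade per
   lead (zero-phase 5–15 Hz Butterworth bandpass, derivative, squaring,
   moving-window integration, adaptive dual thresholds, 200 ms refractory
   period, ±50 ms refinement), then cross-lead **fusion**: candidate
   times from all leads are clustered with a 50 ms tolerance and each
   cluster is fused at its median timing, discarding clusters supported
   by too few leads — which is what removes isolated single-lead
   artifacts.
2. **RR conditioning** — intervals deviating >20% from a five-beat
   moving median are flagged and linearly interpolated; the cleanest
   five-minute window is selected; a 256-interval sequence is extracted
   for the sequence models.
3. **Multidomain HRV descriptors** (32 per recording): time domain
   (mean RR, SDNN, RMSSD, SDSD, pNN50, …), Welch spectral band powers
   (VLF 0.0033–0.04, LF 0.04–0.15, HF 0.15–0.40 Hz; LF/HF, normalized
   units, …) and nonlinear indices (Poincaré SD1/SD2 and ellipse area
   S = π·SD1·SD2, sample and approximate entropy, DFA α₁/α₂).
4. **Group statistics** — Shapiro–Wilk normality gate, Kruskal–Wallis
   omnibus, Dunn–Bonferroni post hoc, median (IQR) tables per feature
   and OGTT stage.
5. **Three multimodal classifiers** sharing a late-fusion design,
   z_fusion = [z_RR, z_HRV] ∈ R⁹⁶: a two-block 1D CNN (64/128 filters,
   kernels 5/3) over the 256-interval RR sequence fused with a 64→32 MLP
   over the standardized HRV vector, classified by softmax (model A), by
   a linear one-vs-rest SVM on the fused embeddings (model B), or with a
   64-unit LSTM replacing the flatten stage (model C). Training is Adam
   (10⁻³, batch 32, up to 100 epochs, early stopping) under **strict
   subject-wise partitioning** (80/20 with 10% internal validation; all
   recordings of a subject stay in one partition).
6. **Evaluation** — one-vs-rest confusion metrics, macro/weighted F1,
   balanced accuracy, Cohen's κ, MCC, one-vs-rest ROC/AUC, and
   HRV-branch feature importance by integrated gradients (permutation
   fallback).

A synthetic cohort generator emulates the study design (15/10/15
subjects × 5 stages = 200 recordings; group-specific mean RR, SDNN, band
modulation and fractal scaling; optional 12-lead ECG rendering with
ground-truth beat annotations and injected single-lead artifacts), so
every stage is testable without any data download. See the methods
vignette (`vignettes/hrv-ogtt-methods.Rmd`) for the model details and
numerical conventions.

## Worked example

Generate a small cohort, detect beats on a rendered 12-lead record,
extract features, and train the CNN–MLP classifier:

```r
library(hrvogtt)

## one rendered 5-minute 12-lead record with ground truth
profile <- default_group_profiles()$MetS
rr  <- generate_rr_series(profile, stage = 0, duration = 330, seed = 1)
ecg <- render_multilead_ecg(rr$beat_times, ecg_render_spec(), seed = 2)
ecg
#> MultileadECG: 12 leads x 329981 samples @ 1000 Hz (330.0 s), 391 annotated beats

peaks <- detect_rpeaks(ecg)
detection_performance(peaks$fused_indices, ecg$true_r_indices, ecg$fs)[1:2]
#> $sensitivity
#> [1] 1
#> $ppv
#> [1] 1

## HRV features for the conditioned five-minute segment
seg <- condition_rr(build_rr(peaks))
round(hrv_features(seg)[c("mean_rr", "sdnn", "lf_hf", "sampen", "dfa_alpha1")], 2)
#>    mean_rr       sdnn      lf_hf     sampen dfa_alpha1
#>     838.67      47.11       2.34       1.73       1.02

## end-to-end: 60-subject cohort, subject-wise split, model A
spec <- synthetic_cohort_spec(n_per_group = c(MetS = 20, C = 20, M = 20),
                              seed = 101, duration_s = 330)
smp   <- multimodal_samples(generate_cohort(spec))
split <- subject_wise_split(data.frame(subject_id = smp$subject_id,
                                       group = as.character(smp$y)), seed = 1)
model <- train_model(build_model(variant = "A", seed = 1), smp, split,
                     train_config(max_epochs = 25, patience = 8, seed = 1))
test  <- split$subject_id[split$partition == "test"]
idx   <- which(smp$subject_id %in% test)
pred  <- predict(model, smp$X[idx, ], smp$H[idx, ])
performance_report(smp$y[idx], pred$labels, pred$scores)
#> Accuracy 0.867 | macro F1 0.862 | balanced acc 0.867 | kappa 0.800 | MCC 0.805 | macro AUC 0.939
```

The detector finds every annotated beat with no false positives on a
clean synthetic record, and the feature vector reproduces the
generator's mean RR/SDNN targets for the MetS profile (838.7 / 47.1 ms
against targets 842.8 / 47.6 ms). The classifier separates the three
synthetic phenotypes on held-out subjects; this particular split is one
of the harder draws (macro-F1 0.86), with typical splits around 0.95 —
the errors concentrate on post-load metabolic-syndrome recordings whose
variability converges into the control range, a deliberate property of
the generator (see the methods vignette).

`run_pipeline(pipeline_config(...))` chains all stages (simulate or load
→ detect → condition → features → statistics → train → evaluate) into a
run directory with CSV/JSON artifacts and a provenance manifest;
`inst/scripts/hrvogtt-pipeline.R` is a thin command-line wrapper around
it.

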