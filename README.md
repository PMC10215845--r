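# mhdnet

R-peak detection in ECG recorded **inside MRI scanners**, where the
magnetohydrodynamic (MHD) effect — the voltage induced by conductive blood
flowing through the static field — superimposes on the ECG and, at high
field strengths, inflates the T-wave until it can eclipse the R-peak.
Detectors that look for the largest deflection then fail, yet R-peak times
are exactly what cardiac-gated imaging and in-bore patient monitoring need.

`mhdnet` is for researchers working with 3 T / 7 T ECG recordings (e.g. the
PhysioNet recordings of ECG under static MRI fields) and for anyone who
wants a fully self-contained, CPU-only reference implementation of
operational-neural-network segmentation for 1D biosignals.

## The method

Detection is posed as 1D segmentation: each annotated R-peak is painted
into a rectangular pulse of height 1 and 13 samples (≈12.7 ms at 1024 Hz),
and a network maps a 4-s, 3-lead window (leads I, II, III) to a per-sample
probability of lying inside a pulse.

The network's unit is the *generative neuron* of self-organizing
operational neural networks (Self-ONN): convolution generalized to a
learnable polynomial,

    f(x) = b + w₁ ⋆ x + w₂ ⋆ x² + … + w_q ⋆ x^q ,      (q = 3)

with x^k the elementwise power of the input and ⋆ zero-padded
cross-correlation; q = 1 recovers an ordinary CNN layer.  The architecture
is a 4-level encoder/decoder (filters 16→256, kernel 11, instance norm +
tanh, max-pool / linear-upsample by 2) with **attention-gated skip
connections** (a learned multiplicative gate in (0,1) computed from encoder
and coarser decoder features) and a **feature-pyramid head** that fuses
decoder levels 1–3 before a kernel-1 output layer.  Training: binary
cross-entropy on sigmoid logits, Adam 1e-3, batch 128, 100 epochs,
subject-wise 5-fold splits (3 train / 1 validation / 1 test), best epoch by
validation DSC.

Scoring: samplewise IoU/DSC for the masks; recall / precision /
F1 = TP/(TP + ½(FP+FN)) for peaks under a 70-ms tolerance (greedy
one-to-one matching); heart-rate agreement via Pearson correlation and
Bland–Altman limits (bias ± 1.96 sd).

Everything — the polynomial convolution with its hand-derived backward
pass, the attention gates, the optimizer — is implemented in this package
(R + RcppArmadillo); a nested-loop oracle and finite-difference gradient
checks guard the compiled kernels.  A synthetic 3-lead generator with a
controllable MHD-like artifact (known ground-truth R locations, "3T-like"
and "7T-like" presets) makes the whole pipeline runnable without any
download.

## Worked example

A miniature study, end to end (≈½ minute on one CPU; 256 Hz synthetic
records so the windows are 1024 samples):

```r
library(mhdnet)

gen  <- synth_preset("7T", n_subjects = 5, records_per_subject = 1,
                     duration_s = 20, fs = 256, seed = 42)
dir  <- tempfile(); make_synthetic_dataset(gen, dir)
recs <- lapply(load_dataset(dir, "synthetic"), preprocess_record)

split <- subject_folds(recs, n_folds = 5, seed = 42)
rot   <- fold_rotation(split, 1)          # 3 train / 1 val / 1 test subjects
subj  <- sapply(recs, `[[`, "subject_id")

fit <- mhdnet_fit(
  segment_records(recs[subj %in% rot$train], overlap_frac = 0.75),
  segment_records(recs[subj %in% rot$val],   overlap_frac = 0),
  build_variant("self_attention_mhdnet", levels = 2, base_filters = 8),
  train_control(epochs = 10, batch_size = 32, seed = 42))
print(fit)
#> Fitted R-peak segmentation network
#> mhdnet_config: selfonn (q=3), 2 levels [8, 16] + bottleneck 32, kernel 11,
#>   activation tanh, attention on, 3 -> 1 channels
#>   parameters: 57007
#>   epochs: 10 (best epoch 10, validation DSC 90.43%)
#>   train subjects: subj02, subj03, subj04
#>   val subjects:   subj05

res <- evaluate_records(fit, recs[subj %in% rot$test])
str(res$detection)
#> List of 3
#>  $ recall_pct   : num 100
#>  $ precision_pct: num 96
#>  $ f1_pct       : num 98
res$hr
#> agreement over 23 pairs: PCC 0.9810, bias 0.012 bpm, 95% LoA [-0.999, 1.022]
```

`res$detection` says every held-out R-peak was recovered within 70 ms
despite the T-wave exceeding the R-peak in amplitude (one spurious extra
detection costs 4 points of precision at this miniature scale); `res$hr`
says the heart rate derived from detected peaks tracks the true
beat-to-beat rate with negligible bias.  (Numbers from the run above; the larger packaged
study at 1024 Hz is in `tests/testthat/test-acceptance.R`.)

The same pipeline is scriptable from a shell via YAML configs:

```sh
Rscript inst/cli/mhdnet.R simulate  --config run.yaml
Rscript inst/cli/mhdnet.R train     --config run.yaml
Rscript inst/cli/mhdnet.R evaluate  --config run.yaml
Rscript inst/cli/mhdnet.R crossval  --config run.yaml
```

## Package layout

| Where | What |
|---|---|
| `R/signal_io.R` | WFDB-compatible reader/writer, manifest-driven datasets |
| `R/preprocess.R` | zero-phase 0.05–100 Hz bandpass + 50 Hz notch |
| `R/labeling.R` | pulse-train targets, windowing, subject-wise folds |
| `R/selfonn.R`, `src/` | generative-neuron layer + brute-force oracle |
| `R/network.R` | encoder/decoder, attention gates, FPN head, backward pass |
| `R/training.R` | `mhdnet_fit()` and S3 methods, Adam, prediction |
| `R/evaluation.R` | peak extraction, 70-ms matching, IoU/DSC, Bland–Altman |
| `R/synthetic.R` | 3-lead generator with MHD-like artifact |
| `R/runconfig.R`, `inst/cli/` | YAML runs: simulate / preprocess / train / evaluate / crossval |
| `vignettes/mhdnet-methods.Rmd` | the model, assumptions and design choices |
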