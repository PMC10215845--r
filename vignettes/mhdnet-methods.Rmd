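---
title: "Detecting R-peaks in MHD-corrupted ECG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting R-peaks in MHD-corrupted ECG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An ECG recorded inside an MRI bore is corrupted by the magnetohydrodynamic
(MHD) effect: blood is a conductive fluid, and its flow through the static
field induces a voltage that superimposes on the body-surface potentials.
The distortion grows with field strength and is concentrated around systolic
ejection, so its most damaging signature is an inflated T-wave that — at 7 T
— can exceed the R-peak in amplitude.  Conventional QRS detectors that key
on "the largest deflection" then fail, which matters twice over: R-peaks
trigger cardiac-gated image acquisition, and they are the basis of heart-rate
monitoring for patients who cannot be observed directly inside the scanner.

`mhdnet` treats detection as 1D semantic segmentation.  Each annotated
R-peak is painted into a rectangular pulse of height 1 and 13 samples
(~12.7 ms at the native 1024 Hz), and a neural network maps a 4-s, 3-lead
ECG window (leads I, II, III) to a per-sample probability that the sample
lies inside such a pulse.  Peak locations are then read off the predicted
mask.

## The generative-neuron (Self-ONN) layer

The network's convolution is generalized to a *generative neuron*: instead
of a single linear kernel, each connection carries a learnable polynomial

$$ f(x) \;=\; b + w_1 x + w_2 x^2 + \dots + w_q x^q , $$

a truncated Taylor-style expansion of an arbitrary nodal nonlinearity.
Lifted to multichannel 1D signals, the layer computes

$$ y_o \;=\; b_o + \sum_{k=1}^{q} w_{k,o} \star x^{\circ k} , $$

where $x^{\circ k}$ is the elementwise $k$-th power of the layer input and
$\star$ is zero-padded ("same") cross-correlation.  With $q = 1$ this is an
ordinary convolution layer, which is exactly how the CNN ablation baseline
is built.  The package uses $q = 3$ throughout, follows each operational
layer with instance normalization and `tanh` (bounding activations to
$(-1, 1)$, which keeps the powers from exploding), and treats the bias as
per-output-channel — the natural reading of the scalar expansion above.

Two numerical choices are worth recording:

* **Initialization.**  Kernels are drawn with variance scaled by the fan-in
  ($\mathrm{sd} = \sqrt{1/(C\,K)}$), and the bank for power $k$ is shrunk by
  $1/k!$.  At initialization the layer therefore behaves like its linear
  term with small polynomial corrections — mirroring the Taylor structure —
  and activations start inside the quasi-linear range of `tanh`.
* **Verification.**  The vectorized forward pass (tap-sliced GEMMs over a
  powers-stacked input, in compiled code) is tested against an
  independently written nested-loop oracle, and the hand-derived backward
  pass against central finite differences, on randomized small cases.

## Architecture

The segmentation network is a 4-level encoder/decoder with a feature-pyramid
output head:

* **Encoder.**  One operational block per level (Self-ONN convolution,
  kernel 11 → instance norm → `tanh`), then max-pooling by 2.  Filters
  double per level: 16, 32, 64, 128, with a 256-filter bottleneck block.
* **Decoder.**  Per level: linear ×2 upsampling of the deeper map,
  concatenation with the (gated) encoder skip, then one operational block
  mirroring the encoder widths.
* **Attention gates.**  Each skip is multiplied by a learned gate in
  $(0,1)$: the encoder signal (level $i$) and the coarser decoder signal
  (level $i+1$, twice the channels, half the length) each pass a kernel-1
  operational layer to the encoder width plus instance norm; the decoder
  branch is upsampled ×2; their sum passes `tanh`, then a kernel-1 layer to
  one channel, instance norm and a sigmoid.  Because the gate is bounded,
  the gated skip never exceeds the encoder signal elementwise — a property
  the tests assert.  Both gate branches are projected to the *encoder*
  width; the two inputs have different widths, and the summation forces one
  common width, so the skip side's width is the coherent choice.  All four
  skips are gated uniformly, including the bottleneck-fed one.
* **Output head.**  Decoder maps of levels 1–3 (16 + 32 + 64 = 112
  channels) are interpolated to full length, concatenated, and reduced to
  one channel by a kernel-1 operational layer.  The head emits raw logits;
  the loss applies the sigmoid.

One block per level (rather than the two-convolution U-Net convention) is a
deliberate reading of the architecture description, and is also the cheaper
choice on CPU.  With attention off the skip reduces to plain concatenation,
and with `q = 1` + ReLU the model becomes the CNN-FPN baseline: the three
ablation variants differ only in the mechanisms under study
(`build_variant()`).

## Training protocol

Records are cleaned, windowed to 4 s, and per-channel z-scored (amplitude
differs wildly between field-strength regimes; the annotation geometry does
not).  Training windows overlap 75% as augmentation; validation and test
windows do not overlap, since the overlap exists to enlarge the training
set, not to multiply evaluation samples.  Subjects are shuffled with a
seeded RNG and dealt round-robin into 5 folds, so all records of a subject
share a fold; each cross-validation round uses 3 folds to train, 1 to
validate and 1 to test.

The loss is binary cross-entropy on the sigmoid-squashed single-channel
output — the parsimonious reading of "cross-entropy" for a two-class mask
(the softmax-pair formulation is equivalent).  The ~1.6% positive-class
rate is left unweighted by default; a `pos_weight` knob exists but stays at
1.  Optimization is Adam at a fixed 1e-3, batch 128, 100 epochs, fully
deterministic under the training seed; the kept parameter snapshot is the
epoch with the highest validation DSC ("best model" selection made
concrete).  At prediction time whole records are tiled into non-overlapping
windows; the trailing partial window is zero-padded after standardization
and the prediction cropped back, so peaks near the record end are not
discarded.

## From masks to peaks, and scoring

The mask-to-peak rule is part of this package's contract (the mask is the
model's output; some rule must be fixed): binarize at 0.5, drop runs
shorter than 3 samples, merge runs separated by less than 100 ms, and
report each run's probability argmax.  When the maximum is attained at
several samples — a flat rectangular run — the middle index is returned
(rounding left), so a clean label pulse maps back to its annotated centre.
All four constants are configuration-exposed.

Scoring is two-layered, as the problem demands:

* **Segmentation**: samplewise IoU and DSC in percent (DSC ≥ IoU
  algebraically; two all-zero masks score 100).
* **Detection**: greedy one-to-one matching by increasing time difference
  with tolerance $\lfloor 0.07\,f_s \rfloor$ samples — 71 at 1024 Hz, the
  strict reading of "within 70 ms".  Recall, precision and
  $F_1 = TP/(TP + \tfrac12(FP+FN))$ follow from the matched counts.
  Counts are micro-aggregated over the records of a fold, then averaged
  across folds.
* **Heart rate**: for consecutive annotated peaks that are both matched,
  paired instantaneous rates ($60 f_s/\Delta$) from truth and prediction
  feed Pearson correlation and Bland–Altman bias ± 1.96 sd limits.

Degenerate inputs follow explicit rules rather than NaNs: 0/0 detection
ratios report 0 with a warning, zero-variance series make the correlation
`NA` with a warning.

## Preprocessing

The cleaning chain is a 0.05–100 Hz bandpass and a 50 Hz notch (Q = 30),
both zero-phase, because the labels are 13 samples wide and a phase shift
of even a few samples would corrupt every downstream number.  The filter
family and order are this package's choice (4th-order Butterworth halves;
standard ECG practice).  Three numerical points:

* The bandpass is a cascade of high-pass and low-pass second-order sections
  (bilinear biquads with the Butterworth Q ladder).  A monolithic 8-pole
  bandpass with a 0.05 Hz corner at 1024 Hz puts all poles within ~1e-3 of
  $z = 1$; in direct form its coefficient rounding visibly distorts the
  passband (tens of percent), which is why the cascade is used.
* Zero-phase filtering pads by odd extension and seeds the filter state
  with its exact constant-input steady state, computed in closed form
  (the usual linear-solve formulation is numerically singular this close to
  the unit circle).  A constant input thus returns exactly its (zero)
  high-pass response from the first sample.
* The pad length scales with the slowest pole's time constant, capped at
  the signal length; edge transients of the 0.05 Hz corner would otherwise
  bleed seconds into the record.

Records are filtered whole, then windowed, so window edges see no filter
transients.

## The synthetic study

No raw scanner recordings ship with the package, so the generator is a
first-class module that emulates what the method needs to be exercised
end-to-end: 3-lead ECG at 1024 Hz with known truth.  Each beat is a sum of
Gaussian bumps (P, Q, R, S, T) with fixed timings relative to R; R-R
intervals are lognormal around the subject's rate (sdlog 0.05, clamped to
0.3–2 s); subjects differ in rate (normal, sd 5 bpm around 70) and
amplitude (±20%); each lead receives the source with distinct
polarity/scale (0.7, 1.0, −0.5) plus baseline wander (< 0.5 Hz sinusoids,
amplitude 0.15), white noise (sd 0.05) and a 50 Hz component (0.05) —
the artifacts the preprocessing chain exists to remove.  The MHD effect is
modelled by its dominant observable: the T-bump amplitude is scaled by
$(1 + 3\,s)$ with severity $s$, so the "3T-like" preset ($s = 0.5$) makes T
comparable to R and the "7T-like" preset ($s = 1$) makes T exceed R
(1.2 vs 1.0).  Crucially the labels are the R-bump centres, known
analytically and *independent of severity and noise* — the artifact
corrupts morphology, never truth — which is the property an acceptance
surface needs most.

A deliberately simple template model was chosen over a coupled-ODE
simulator: it is fast, deterministic under a single seed (per-record
streams are derived from the master seed and the record id), and its truth
is exact.  What it does **not** emulate: real MHD morphology beyond the
T-wave (flow-dependent multi-bump structure), gradient-switching and RF
artifacts, electrode motion, arrhythmia, or inter-lead timing differences.
Passing the synthetic study therefore demonstrates that the pipeline,
optimization and scoring are correct and that the model can learn to ignore
a dominant T-wave; it does not certify performance on real 3 T/7 T
recordings, which require the original data and full-scale training.

## Problem sizes

The packaged tests run a scaled-down version of the study: 5 subjects × two
60-s records ("7T-like" preset), one 3/1/1 subject split, and a reduced
model (2 levels, 8 base filters, kernel 11, q = 3) trained 15 epochs at
batch 32 — sizes chosen so the full suite exercises every stage, including
optimization, in minutes on one CPU.  Module tests use 256 Hz records
(1024-sample windows) for the same reason.  The full-scale protocol
(4 levels, 16→256 filters, batch 128, 100 epochs, five-fold rotation) is
the package default and runs unchanged via `run_crossval()` given real
WFDB data and time.

## Known limitations

* Indices are 1-based throughout (R convention); time is
  `(index − 1)/fs`.  WFDB annotation files store 0-based times; the reader
  and writer convert.
* The WFDB support is the subset this pipeline needs: format-16 signals,
  single-segment records, beat-class annotations (SKIP-extended intervals
  handled); it is not a general WFDB implementation.
* Checkpoints are R serialization files (`.rds`) holding the configuration
  (as a YAML text block) and all arrays; reload is bit-exact but not
  portable to other frameworks.
* Training runs on one CPU; there is no accelerator path.  The compiled
  kernels are single-threaded BLAS calls, so wall time scales linearly
  with model size and epochs.
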