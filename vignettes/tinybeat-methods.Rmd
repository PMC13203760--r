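---
title: "Methods: beat classification with a compact quantized 1D CNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beat classification with a compact quantized 1D CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinybeat)
```

tinybeat implements a complete single-lead ECG beat-classification
pipeline of the kind deployed on microcontroller-class hardware: signal
conditioning, QRS detection, beat segmentation, a compact float 1D
convolutional network, post-training full-integer (INT8) quantization,
and an integer-only inference engine with memory accounting.  This
vignette is the package's account of the underlying methods, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic test bed does and does not show.

## The classification problem

The unit of analysis is a single heartbeat: a 250-sample window of
Lead II ECG at 360 Hz (about 0.7 s), centred on the R peak and min–max
normalized to [0, 1].  Beats are labelled with a reduced three-class
scheme derived from the AAMI taxonomy: normal-like (N — includes bundle
branch block and escape beats), ventricular ectopic (V), and
supraventricular ectopic (S).  Fusion, paced and unknown beats are
excluded.  `map_annotation_symbol()` encodes the standard grouping
(N, L, R, e, j → N; A, a, J, S → S; V, E → V; everything else excluded)
and accepts a table override.

Beat-wise evaluation with no patient separation is deliberately the
benchmark protocol here: segments from one subject may appear on both
sides of a split, so reported numbers are technical benchmark figures,
not patient-independent clinical estimates.

## Preprocessing

Raw ECG is filtered with a fourth-order digital Butterworth band-pass,
0.5–40 Hz: the low corner removes baseline wander (respiration,
electrode drift), the high corner attenuates muscle noise and powerline
interference while keeping P–QRS–T morphology.  The transfer function
comes from `signal::butter()`; it is realized as cascaded biquads
because the 0.5 Hz corner at 360 Hz puts poles very close to the unit
circle, where a cascade is better conditioned than a direct form.

Filtering is zero-phase (forward–backward), so the effective magnitude
response is the square of the single-pass response and QRS landmarks are
not displaced — important because beat windows are centred on the R
apex.  Two numerical details are the package's own choices (the
realization and padding are not dictated by the method): edges are
padded by even extension of length `3 * (order + 1)` samples, and each
pass starts from step-matched initial conditions (the steady state of
the cascade for a unit step, scaled to the first padded sample), which
suppresses the long start-up transient the 0.5 Hz corner would otherwise
produce.

Each extracted beat window is normalized independently by its own
minimum and maximum ("per-segment" min–max).  The pipeline order is
filter → segment → normalize per segment; per-segment normalization is
the more specific rule and makes each model input self-contained.
Constant (flat) windows have no defined normalization and carry no
morphology; they are dropped and counted rather than zero-filled.

## QRS detection

`pan_tompkins_detect()` is the classic chain: five-point derivative
(applied centred so it adds no group delay), squaring, 150 ms
moving-window integration, and an adaptive threshold
`npk + 0.25 (spk − npk)` over running signal/noise peak estimates
(`0.125 · peak + 0.875 · estimate`) with a 200 ms refractory period.
Accepted detections are refined to the local maximum of the filtered
signal within ±100 ms, so the stored index is the R apex used for
window centring.

Two adaptations were needed and are package design choices.  First, the
signal-peak estimate is initialized at half the maximum of the 2 s
learning window: wide ventricular complexes carry roughly four times
less slope energy than narrow beats, and a max-initialized threshold
rejects them outright.  Second, a search-back stage is included: when an
RR gap exceeds 1.66× the median RR, the gap is re-scanned at half the
running threshold and the largest qualifying integrated peak is
accepted.  Without search-back, a run of normal beats drags the
threshold to a level at which wide-QRS beats are intermittently lost;
with it the detector reaches unit sensitivity and positive predictivity
on the synthetic test bed at 20 dB SNR.

Training datasets centre windows on annotated R samples (benchmark
practice); the detector drives the label-free inference path.  Both
modes are available in `build_dataset()`.

## The float model

The canonical architecture (`beat_cnn_architecture("table1")`) is

    Conv1D(16, k=3, ReLU) → MaxPool(2) → Conv1D(32, k=3, ReLU)
      → Flatten → Dense(64, ReLU) → Dense(3, softmax)

on (250, 1) inputs with valid convolutions, giving shapes
(248, 16) → (124, 16) → (122, 32) → 3904 → 64 → 3.  Batch normalization
follows each convolution and 20% dropout precedes the output layer; both
are on by default and toggleable.  Counted layerwise, this topology has
251,747 trainable parameters without batch norm (the 3904 → 64 dense
layer alone contributes 249,920) and 251,843 with it.  A commonly quoted
"≈18.5k parameter" figure for this model family is not consistent with
this topology; `beat_cnn_architecture("reduced")` (an extra MaxPool(2)
after the second convolution and a 9-unit hidden dense layer, ~19.3k
parameters) is provided as an explicit preset for that regime, and the
package always reports measured counts.

Training (`beat_cnn()`) is Adam (learning rate 0.001), batch size 32,
categorical cross-entropy, up to 100 epochs with early stopping at
patience 10 on validation loss and best-weights restoration.  Weights
are initialized uniformly with Glorot-style bounds
±√(6/(fan_in+fan_out)).  The forward/backward pass is plain matrix
arithmetic (im2col convolutions), single-threaded and fully
deterministic under one seed that drives initialization, shuffling and
dropout.  Two numerical choices matter on small datasets:

* Batch-norm inference statistics are re-estimated exactly over a fixed
  512-beat training subset at the end of every epoch.  With few
  optimizer steps per epoch, momentum-type running averages lag the
  rapidly growing weights and inference-mode accuracy collapses even as
  train-mode accuracy is perfect; exact re-estimation removes the lag at
  the cost of one extra forward pass per epoch.
* Early stopping counts an improvement only when validation loss drops
  by more than `min_delta = 1e-4`.  On cleanly separable data the loss
  otherwise keeps creeping down by ~1e-8 per epoch and training runs to
  the epoch cap for no accuracy change.

## INT8 quantization

`quantize()` converts a trained model to a full-integer representation:

* weights: per-tensor symmetric, `scale = max|w| / 127`, zero point 0
  (per-channel is a possible refinement, not currently exposed);
* activations: per-tensor asymmetric over calibrated ranges,
  `scale = (max − min)/255`,
  `zero_point = round(−128 − min/scale)` clamped to [−128, 127];
* biases: int32 at `s_in · s_w`;
* batch norm folded exactly into the preceding convolution beforehand.

Calibration runs the float model over a representative set (default: a
seeded 200-segment subsample of the training data) and records per-tensor
min/max, widened so zero is always representable.  Each compute layer
gets a fixed-point requantization constant: the real multiplier
`M = s_in · s_w / s_out` is written as `m0 · 2⁻³¹ · 2⁻ⁿ` with
`m0 ∈ [2³⁰, 2³¹)`, accurate to better than 2⁻²⁴ relative.  Rounding is
half away from zero for values; the activation zero point uses standard
round-half-even (the convention that keeps a symmetric range's zero
point at exactly 0).  Int8 weight tensors occupy exactly 25% of their
float32 bytes — the "75% smaller" headline is a storage identity for the
tensor payloads, not an empirical result.

The portable container is `magic | version | JSON metadata | int8
weights | int32 biases | float64 scales`; the same bytes are the Flash
payload for `footprint()` and the body of the xxd-style `model.h`
export.

## Integer-only inference

`classify()` and `predict()` on a quantized model execute entirely in
integer arithmetic: int8 tensors, int32 accumulators
(`acc = Σ (q_in − zp_in) q_w + bias`), fixed-point requantization with
an int64 product, output zero-point shift, saturation to [−128, 127],
and ReLU fused as a clamp at the output zero point.  Softmax is monotone
and therefore excluded from the label path — classification is argmax
over int8 logits, as a device without a floating-point unit would
compute it.  Probabilities, when requested, are a display feature
computed by dequantizing the logits in floating point and flagged as
such.  The test suite carries an independent pure-R integer engine that
asserts every intermediate is an exact integer (an arithmetic trace of
the FPU-less path) and must agree with the compiled kernels exactly.

`footprint()` accounts memory the way a static-buffer microcontroller
deployment would: Flash is the serialized payload size; SRAM is the peak
over a two-buffer ping-pong schedule of input buffer + output buffer +
one int32 output tile, at native widths.  For the canonical topology
this peak is ~5.9 KB (the 122×32 conv output next to the 124×16 pooled
input) and Flash is ~247 KB at one byte per weight — reported as
measured; kilobyte-scale deployments of this pipeline correspond to the
reduced-architecture regime, not the canonical topology.

## Evaluation

`confusion()`, `metrics_from_confusion()` and `auc_ovr()` implement the
AAMI-style report: per-class one-vs-rest precision/recall/F1, overall
accuracy, and both support-weighted averages
(`M_weighted = Σ nᵢ Mᵢ / Σ nᵢ`) and macro averages (the two coincide for
balanced data; both are reported because published tables rarely say
which they use).  Zero-denominator metrics are reported as 0 with a
flag.  Multiclass AUC is one-vs-rest via the midrank statistic with the
same support weighting — one of several defensible constructions, chosen
and documented here.  `stratified_split()` (60/20/20 by default) and
`crossval_beat_cnn()` (stratified five-fold; four folds train, one
tests; a stratified 20% slice of each training side drives early
stopping) are beat-wise.  `agreement_report()` compares float and INT8
models: accuracies, their difference in percentage points, pooled
probability R², and argmax agreement.

## The synthetic test bed

`generate_record()` builds beats as sums of Gaussian bumps with
class-specific templates: N has full PQRST with a narrow QRS; V has a
wide QRS (>120 ms above half amplitude), no P wave and a discordant T;
S has a narrow QRS, no P wave and a shortened coupling interval (0.65 of
the drawn RR).  RR intervals jitter uniformly ±10% around 72 beats/min.
Noise defaults — 0.1 mV baseline wander at 0.3 Hz, 0.05 mV powerline at
60 Hz, 0.02 mV white — are modest, realistic magnitudes placed
deliberately inside the filter's stop bands so the preprocessing is
exercised.  One seeded generator drives each record; ground-truth R
positions and labels are exact by construction, and records can be
written in WFDB form to exercise the reader.

What this test bed shows: that every stage of the pipeline is wired
correctly, deterministic, and numerically faithful (float-vs-INT8
agreement, detector operating points, metric identities).  What it does
not show: performance on real ECG.  The three synthetic classes are
cleanly separable by design, so classification accuracies near 1.0 here
say nothing about accuracy on clinical recordings, where inter-patient
morphology variation, noise and class imbalance dominate.  Benchmark
figures on real data must come from running the same pipeline on an
annotated database via `read_wfdb_record()`.

Problem sizes used by the shipped tests and the reproduction script —
3,000 training beats, 600 held-out test beats, five-fold
cross-validation at up to 12 epochs per fold — are the package's chosen
desk-scale study conditions: large enough that splits, calibration
subsampling and fold summaries are meaningful, small enough to run
comfortably on one CPU.

## Known limitations

* Single lead, three classes, no resampling: non-360 Hz records are
  rejected rather than resampled, and the full five-class AAMI scheme is
  out of scope.
* The detector has no T-wave discrimination beyond the refractory
  period, and no per-channel quantization or quantization-aware training
  is provided.
* Memory accounting models a specific (two-buffer) execution schedule;
  real inference stacks differ in scratch layout and alignment.
* The WFDB support is a minimal subset (formats 16 and 212, MIT
  annotations), sufficient for the standard arrhythmia-database layout
  and the package's own records.

## A worked miniature

```{r example, eval = FALSE}
ds <- synth_beat_dataset(900, seed = 1)
sp <- stratified_split(ds, seed = 2)
model <- beat_cnn(sp$train, validation = sp$validation,
                  control = beat_cnn_control(epochs = 12), seed = 3)
qm <- quantize(model, representative = sp$train, seed = 4)
agreement_report(model, qm, sp$test)
footprint(qm)
```
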