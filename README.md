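# tinybeat

Heartbeat classification with a compact, quantized 1D convolutional
network — the full TinyML-style pipeline, in R, runnable end to end with
no external data.

## The problem

Automatic arrhythmia screening on microcontroller-class hardware works
beat by beat: a single-lead ECG (Lead II, 360 Hz) is band-pass filtered,
QRS complexes are detected, each heartbeat is cut into a 250-sample
window (~0.7 s) centred on the R peak and min–max normalized, and a
small convolutional network assigns one of three AAMI-style classes —
normal-like (N), ventricular ectopic (V), supraventricular ectopic (S).
To run on a device without a floating-point unit, the trained float
model is converted by post-training quantization to 8-bit integers and
executed with integer arithmetic only.

tinybeat implements every stage of that pipeline for researchers and
engineers who want to study it quantitatively on a desktop:

* **Preprocessing** — fourth-order Butterworth band-pass (0.5–40 Hz) as
  cascaded biquads, applied forward–backward (zero phase); per-segment
  min–max normalization `x_norm(t) = (x(t) − x_min)/(x_max − x_min)`.
* **Beat detection/segmentation** — adapted Pan–Tompkins chain
  (derivative → squaring → 150 ms moving-window integration → adaptive
  threshold `npk + 0.25(spk − npk)` with 200 ms refractory and
  search-back), 250-sample windows `[r−125, r+125)`.
* **Model** — Conv1D(16,3) → MaxPool(2) → Conv1D(32,3) → Flatten →
  Dense(64) → Dense(3, softmax) with batch norm and 20% dropout, trained
  with Adam (lr 0.001, batch 32, ≤100 epochs, early stopping patience
  10); implemented in plain matrix arithmetic, deterministic under a
  seed.
* **Quantization** — full-integer INT8: per-tensor symmetric weights,
  asymmetric activations calibrated on a seeded 200-segment sample,
  int32 biases, fixed-point requantization `m0·2⁻³¹·2⁻ⁿ`; weight
  payloads shrink to exactly 25% of float32.
* **Integer-only inference** — int8/int32 arithmetic end to end (argmax
  over int8 logits; no floating point on the label path), plus
  Flash/SRAM footprint accounting and an xxd-style `model.h` export.
* **Evaluation** — confusion matrices, per-class and support-weighted
  precision/recall/F1, one-vs-rest AUC, stratified 60/20/20 splits,
  stratified five-fold cross-validation, float-vs-INT8 agreement
  (accuracy delta, probability R², argmax agreement).
* **Synthetic ECG generator** — seeded Gaussian-bump PQRST beats with
  class-specific morphology, controlled baseline wander / powerline /
  white noise, exact ground-truth R positions and labels; plus a minimal
  WFDB reader/writer (.hea/.dat formats 16 & 212, .atr annotations) for
  real records in the standard arrhythmia-database layout.

## Worked example

```r
library(tinybeat)

ds    <- synth_beat_dataset(900, seed = 1)          # labelled 250-sample beats
sp    <- stratified_split(ds, seed = 2)             # 60/20/20
model <- beat_cnn(sp$train, validation = sp$validation,
                  control = beat_cnn_control(epochs = 12), seed = 3)
model
#> <beat_cnn> table1 architecture, 251843 parameters, trained 12 epochs (best 2)

qm <- quantize(model, representative = sp$train, seed = 4)
qm
#> <quant_beat_cnn> table1 architecture, INT8 weights (251632 bytes; float32 would be 1006528)

agreement_report(model, qm, sp$test)
#> <agreement_report> n=179
#>   accuracy: float 1.0000, int8 1.0000 (delta 0.00 pp)
#>   probability R^2 1.0000, argmax agreement 1.0000

footprint(qm)
#> <memory_footprint> flash 247.0 KB, sram peak 5.88 KB
#>  layer    type in_bytes out_bytes scratch_bytes total
#>      1    conv      250      3968            64  4282
#>      2 maxpool     3968      1984             0  5952
#>      3    conv     1984      3904           128  6016
#>      5   dense     3904        64           256  4224
#>      6   dense       64         3            12    79
```

Reading the output: both models classify the held-out synthetic beats
perfectly and agree with each other beat for beat (`delta 0.00 pp`,
argmax agreement 1.0) — quantization to int8 costs nothing here.  The
int8 weight payload (251,632 bytes) is exactly a quarter of its float32
size.  Flash is the serialized model; the SRAM peak (5.88 KB) is the
largest pair of live activation buffers plus one int32 accumulator tile
under a two-buffer schedule.  Synthetic classes are separable by
design — accuracies near 1.0 validate the pipeline, not clinical
performance (see the methods vignette).

A thin CLI wraps the same stages:

```sh
exec/tinybeat simulate segment train quantize evaluate footprint \
    --n-beats 3000 --seed 1 --out run1
```

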