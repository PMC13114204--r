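---
title: "Methods: multiscale cosine-convolution seizure detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale cosine-convolution seizure detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coseize)
```

## The detection problem

Long-term scalp EEG monitoring produces many hours of multichannel signal
in which seizures occupy a tiny, patient-specific fraction. `coseize`
implements a patient-specific detector: a separate model is trained,
calibrated and tested on each patient's own recording. A recording is an
18-channel (by default) matrix at 256 Hz with expert seizure annotations as
half-open `[onset, offset)` second intervals; the classifier consumes 4 s
segments (18 × 1024 samples) and emits an ictal probability per segment,
which post-processing turns into detected events.

## The cosine parameterization

Every temporal filter of length $k$ is generated from two scalars,

$$K_m(A, \omega, k) = A \cos\!\big(\omega\,(m - \tfrac{k-1}{2})\big),
\qquad m = 0, \dots, k-1,$$

with amplitude $A$ and angular frequency $\omega$ learnable and
initialized from $\mathcal N(0,1)$. Consequences the package relies on and
tests:

* the centring offset makes every kernel **center-symmetric**, so true
  convolution equals cross-correlation;
* per-kernel parameters drop from $k$ to 2, a relative saving of
  $(k-2)/k$ per swapped kernel;
* at $k = 1$ the kernel degenerates to $[A]$ and $\omega$ is inert;
* $\omega$ is left unconstrained: values beyond $\pi$ alias back into
  band, which training is free to exploit. No bias terms are used in
  cosine layers, keeping the two-parameter accounting exact (a bias can be
  enabled per layer).

Gradients flow to $(A, \omega)$ through the closed form
($\partial K_m/\partial A = \cos(\omega c_m)$,
$\partial K_m/\partial \omega = -A\,c_m \sin(\omega c_m)$ with
$c_m = m - (k-1)/2$), verified in the tests against central finite
differences.

## Architecture

* **Multiscale front end.** Three parallel branches with kernel lengths
  9 / 5 / 1 and 32 filters each (defaults). Each branch applies the
  temporal cosine convolution per electrode (one input channel, shared
  across electrodes), then a standard spatial convolution spanning all 18
  electrodes (this layer is deliberately always standard), batch
  normalization, ReLU, dropout (rate 0.5) and max-pooling (window 12),
  leaving ~85 time bins per branch. Branch outputs concatenate along the
  time axis (channel-axis concatenation is available for experimentation).
* **Two-stream modules (×2).** Each module feeds its input to a shallow
  stream — a single cosine convolution, $k = 3$, followed only by ReLU, no
  normalization or regularization, preserving low-level temporal structure
  — and a deep stream — twice (cosine conv $k=3$ → layer normalization →
  ReLU → spatial dropout of whole feature channels, rate 0.25). With valid
  padding the streams end two samples apart, so both are right-cropped to
  the common width and concatenated along channels; `merge = "add"` is
  offered but requires equal shapes and errors otherwise.
* **Classifier.** Flatten → 64 hidden units (ReLU) → 2-way softmax.

The original description leaves activation functions unstated; ReLU after
each normalization (and after the shallow conv) is the standard choice and
is what this package uses. The layer order conv → norm → ReLU → dropout →
pool resolves another ambiguity the same way.

The network, including forward and reverse passes, is implemented directly
in R on BLAS matrix products (im2col unrolling); no external deep-learning
runtime is involved. Training uses Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8),
cross-entropy loss, batch size 128, shuffling every epoch, and a stepped
learning rate: 2×10⁻⁴ decayed by 0.89125 every 20 epochs. Because
$0.89125^{20} \approx 0.1$, the printed final rate 2×10⁻⁵ is reached at
epoch 400 and the schedule is clamped there — this honours both published
endpoint values, which a literal 25-decay reading would not. Optimizer
batches are internally processed in gradient-accumulation chunks (default
32 segments) purely to bound peak memory; batch-norm batch statistics are
therefore computed per chunk.

## Data pipeline

* **Filtering.** A 5-level Daubechies-4 DWT with symmetric extension
  decomposes each channel; reconstruction from detail bands d3–d5 only
  retains 4–32 Hz, the clinically relevant range. Filtering runs on the
  continuous recording *before* segmentation so window edges carry no
  transients. The transform is authored in the package (no R wavelet
  package was available) and reproduces the coefficient layout of the
  common Python implementation; reconstruction from all bands is exact to
  ~1e−12 relative.
* **Segmentation and labels.** Windows of $T = 1024$ samples; a segment is
  ictal iff its half-open interval intersects any annotation (any-overlap
  rule). Trailing partial windows are dropped.
* **Training split.** Selected training seizures are concatenated and cut
  with step $\Delta = \lfloor T/n_{over}\rfloor = 204$ at the default
  oversampling rate $n_{over} = 5$ (~80 % overlap). Interictal material
  comes from $2 n_{over}$ seizure-free chunks of length $L_{sz}/2$ each
  ($L_{sz}$ = total training-seizure duration), drawn at uniformly spaced
  positions over the seizure-free sample pool (concatenated virtually, so
  chunks never touch an annotated event) and segmented without overlap —
  interictal:ictal duration ≈ 5:1. A contiguous 20-min seizure-free span
  (the earliest that fits) is reserved for calibration; the rest of the
  recording, in chronological order, is the test stream. Guarantees tested:
  training windows never intersect test-event samples; calibration is
  disjoint from both.
* **Post-processing.** Scores are smoothed with a centred moving average of
  half-window $N$ (boundary windows shrink to the available samples,
  keeping length), thresholded strictly (`score > Thr`), and maximal
  positive runs are dilated by $K$ segments each side (collar; one segment
  = 4 s). `(N, Thr, K)` are calibrated per patient by grid search
  (defaults $N, K \in 0..6$, $Thr \in \{0.1,\dots,0.9\}$): admissible
  points must detect 100 % of the training seizures when the pipeline is
  applied to the training-event score stream; among those, minimize false
  alarms on the calibration stream, breaking ties by fewer alarms, smaller
  $K$, smaller $N$, then $Thr$ nearest 0.5. The calibration objective is a
  design choice of this package (the source material reserves the data but
  does not state the objective).

## Evaluation

Segment metrics are confusion-matrix rates in percent. Event metrics use
any-overlap matching of half-open intervals: a seizure is detected if at
least one predicted event overlaps it (multiple predictions count once);
a predicted event overlapping no seizure is false, and FDR is false events
per test hour. AUROC is computed under a fixed 24 s setting for all
patients: a 6-segment asymmetric mean (3 past, current, 2 future — a 24 s
window cannot be odd-symmetric in 4 s segments) smooths the scores, and
the 24 s collar is applied to the *reference labels* (scores are
continuous, so dilating the truth is the coherent reading); the statistic
is the midrank Mann–Whitney formula. Multi-patient summaries offer both
the macro average — whose standard deviation uses the population (n
denominator) convention, the one that reproduces published summary rows —
and the pooled ratio Σdetected/Σmarked, which differ when patients have
unequal event counts.

## Interpretation

Grad-CAM is computed against the concatenated front-end feature map using
the ictal logit (pre-softmax): channel weights are the global average of
the gradient over a (sub-)map, and the map is the rectified weighted sum
of feature channels. For branch attribution the concatenated width $W$ is
split into three contiguous blocks of $\lfloor W/3\rfloor$ with the
remainder assigned to the last block — a deliberate repair of an
inconsistent published split description — each resized to the input
sample axis by linear interpolation and max-normalized (an all-zero map
stays zero; only relative attention is meaningful). The fused map is the
pointwise mean of the three resized maps, re-normalized.

## Synthetic EEG generator

Background is spectrally shaped Gaussian noise (power ∝ $1/f^{\beta}$,
default $\beta = 1$) plus optional sinusoidal rhythms (default: a modest
10 Hz alpha-like component), drawn per channel from counter-based
substreams of one seed so channel count changes never reshuffle other
channels. Seizures inject a shared template — repeating ~3 Hz
spike-and-slow-wave composites, ramped ~6 Hz rhythmic bursts, or isolated
asymmetric sharp waves — scaled by an event gain (relative to the
background SD, default 20 µV) and per-channel random gains in [0.5, 1.5]
to mimic inter-channel ictal coherence. Gain 0 yields an annotated but
signal-free null recording, used to verify that the trained detector
scores at chance (AUROC ≈ 0.5).

What the generator does **not** emulate: real artifact structure
(EMG/EOG, electrode pops), non-stationary background, seizure evolution
and morphology diversity, or inter-patient variability. Passing the
synthetic recovery tests therefore demonstrates that the pipeline's
machinery is correct and sensitive at the configured SNR — not clinical
performance.

## Problem sizes used by the tests and the acceptance script

The reference synthetic patient is 90 min of 18-channel EEG with eight
30 s spike-wave seizures at gain 6 (two for training, six for testing) and
a 20-min calibration span; the desk-scale model halves the default width
(16 filters per branch, 16 two-stream channels) and trains 12 epochs —
about 150 optimizer-visible segments, a few minutes on one CPU core. Unit
tests use smaller models (4 channels, 256-sample windows). These sizes are
the package's chosen study conditions for routine verification; nothing
prevents running the full-width model for 500 epochs on real recordings
via the same functions.

## Known limitations

* Training at published scale (hundreds of hours, 500 epochs per patient)
  is supported by the code paths but slow in plain R; the engine is
  single-threaded apart from BLAS.
* The EDF writer is minimal (for fixtures): 1 s records, no embedded
  annotations (sidecar CSV/JSON is the package's annotation format).
* No artifact-rejection stage beyond the wavelet band-pass is provided.
* `merge = "add"` in the two-stream module requires externally equalized
  stream shapes; the default channel concatenation crops instead.
* Batch-norm statistics depend on the gradient-accumulation chunk size, so
  bitwise training reproducibility holds only for a fixed `microBatch`.
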