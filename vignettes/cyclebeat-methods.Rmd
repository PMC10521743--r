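---
title: "Cyclic latent-trajectory modelling of single-lead ECG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyclic latent-trajectory modelling of single-lead ECG: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Atrial fibrillation (AF) shows itself on a single-lead ECG in two ways: the
RR intervals become erratic, and the P wave — the atrial depolarization that
normally precedes each QRS complex — disappears. `cyclebeat` detects AF by
making both signatures explicit. A recording is decomposed into short
subsequences anchored on R peaks, each subsequence is compressed into the
parameters of a *cyclic latent trajectory*, and the per-beat parameters are
aggregated into one record-level vector for classification.

The trajectory model embeds a subsequence $(s_j, t_j)_{j=1}^n$ as a closed
curve in $\mathbb{R}^d$,

$$\ell(t) = \cos\!\big(2\pi f (t - \tau)\big)\, e_1
          + \sin\!\big(2\pi f (t - \tau)\big)\, e_2
          + \sum_{j=3}^{d} b_j\, e_j,$$

and reconstructs the voltage as $\hat s_j = f_D(\ell(t_j))$ with a decoder
network $f_D$. The first two coordinates traverse the unit circle at pace
$f$ (cycles per second, so the heart rate is $60f$ bpm); the remaining
$d-2$ coordinates are *shape coefficients* constant in time. Three nested
parameterisations are supported:

* **DHB** — frequency $f$, phase shift $\tau$ and shape vector $b$
  ($d$ stored numbers). The shift absorbs the arbitrary starting phase of
  unaligned slices.
* **P-DHB** (pace) — drops $\tau$ ($d-1$ numbers). Valid whenever every
  input starts at an R peak, so all inputs share the cycle origin.
* **S-DHB** (shape) — additionally drops $f$ ($d-2$ numbers). Valid for
  single heartbeats whose time axis has been normalized to one cycle of
  phase in $[0,1)$; the embedding then carries morphology only, which makes
  it invariant to uniform time rescaling and therefore robust to sampling
  rate changes.

Reconstruction quality is measured by the per-sequence root-mean-square
error $\mathrm{RMSE}(s, \hat s) = \sqrt{\tfrac1n \sum_k (s_k - \hat s_k)^2}$
in mV, which also serves as the anomaly score for noise detection: a model
trained on clean heartbeats reconstructs noise-only records poorly, so the
mean per-beat RMSE of a record ranks its "noisiness".

## Pipeline stages and their parameters

**R-peak detection** is the classic Pan-Tompkins chain: 5–15 Hz band-pass
(zero-phase, forward-backward second-order Butterworth sections), five-point
derivative, squaring, 150 ms moving-window integration, adaptive
dual-threshold peak picking with a 200 ms refractory period and a
search-back pass at 1.66 times the running RR average. All stage constants
follow the original 1985 design. Two deterministic choices close gaps the
original leaves open: thresholds are warm-started from the first 2 s of the
integrated signal, and each detection is refined to the raw-signal argmax
within ±50 ms so slices anchor on the R apex. The signal mean is subtracted
up front, which makes detection exactly invariant to constant voltage
offsets.

**Slicing** offers three strategies: random slices (uniform start, duration
uniform in $[1.5, 4.0]$ s), R-peak-aligned slices (same durations, starts
restricted to detected peaks), and heartbeat extraction (half-open sample
intervals $[r_k, r_{k+1})$, so beats tile the signal without overlap). The
half-open convention assigns each R peak to the beat it starts. Beats with
RR outside $[0.3, 2.0]$ s — detector glitches or pauses — are dropped and
counted. Sample indices are 0-based throughout; sample $k$ occurs at $k/f_s$
seconds.

**Encoding.** The encoder is a fully connected network (two tanh hidden
layers, 64 units each) over the slice resampled to 96 points by linear
interpolation, with the slice duration appended as an extra feature for the
pace-carrying variants; S-DHB omits the duration input, which is what makes
its time-stretch invariance exact by construction. Heads emit the parameter
groups; the frequency head is $\mathrm{softplus}(x) + 0.1$, enforcing
$f > 0$ structurally with a 0.1 Hz floor, and its bias is initialized so the
initial pace is about 1 Hz, a typical resting heart rate. The decoder is a
separate $d \to 64 \to 64 \to 1$ tanh network. A convolutional encoder would
be the conventional choice at data-center scale; the fully connected stack
was chosen because it trains in seconds on one CPU with plain BLAS matrix
products while leaving every contract of the embedding unchanged.

**Training** minimizes the mean over slices of the per-slice mean squared
reconstruction error (so short beats are not down-weighted relative to long
ones) with Adam (learning rate $10^{-3}$, batch 64), the loss evaluated on a
48-point resampling of each slice. Initialization and shuffling are fully
determined by the configured seed. No input filtering or normalization is
applied at any point.

One training detail deserves emphasis. For a *single* heartbeat, plain
reconstruction does not identify the pace: any $f$ with $f \cdot T \le 1$
(with $T$ the beat duration) traces an injective arc that a flexible decoder
fits equally well, so $f$ is only bounded above, not pinned. Heartbeats,
however, tile a locally periodic signal. The package therefore evaluates the
heartbeat reconstruction loss over two cycle repetitions (targets duplicated
at $t$ and $t + T$): if the latent loop fails to close after exactly one
beat, the second repetition lands on a mismatched stretch of the curve and
is penalized, which pins $f \cdot T = 1$. This is what makes the per-beat
heart-rate readout $60f$ meaningful. The number of repetitions is a
configuration parameter (`cycle_reps`, default 2; 1 disables the
constraint).

**Aggregation.** Mean aggregation averages the flattened parameter vectors
coordinate-wise — including $f$ and $\tau$, accepted deliberately for
fidelity to the plain averaging definition even though averaging a phase
across beats is fragile. It is permutation-invariant, hence blind to rhythm
dynamics. The recurrent alternative reads the ordered sequence with a
bidirectional LSTM (32 hidden units per direction, forget-gate bias 1) and
concatenates the final hidden states; since aggregation has no loss of its
own, it is trained end-to-end with its softmax classifier head. Sequences
longer than 512 elements are subsampled uniformly — hours-long Holter-style
records would otherwise produce impractical recurrence lengths.

**Classification and evaluation.** The classifier head is a 64–32 tanh
multilayer perceptron with softmax output, trained with cross-entropy on
internally standardized features. Binary AF evaluation thresholds the AF
probability at 0.5 and reports sensitivity, specificity, PPV, accuracy, F1
(the harmonic mean of PPV and sensitivity) and the rank-statistic AUC;
metrics whose denominator is empty are reported as missing rather than 0.
Cross-validation uses k stratified folds of sizes differing by at most one
(stratification guards against folds that lack a rare class entirely),
each fold tested once against a model trained on the rest, hyperparameters
fixed across folds; results are reported as mean ± standard deviation over
folds. For windowed evaluation, 30-beat sliding windows are labeled by one
of three rules: the middle beat's flag (0-based index 15 — an even window
has no true center, so the index is a flag-controlled convention), the
majority rule (AF iff at least 15 of 30 beats are AF), or a threshold rule
(AF iff the AF fraction reaches $p$, default 0.8). The threshold comparison
is non-strict by default because 80% of 30 beats is attainable exactly
(24/30); a `strict` flag switches the convention.

## The synthetic generator: what it emulates and what it does not

Every stage is exercised against generated single-lead records (default
300 Hz, ±5 mV range) with known ground truth. Each beat is a sum of five
Gaussian bumps — P, Q, R, S, T with amplitudes (0.15, −0.1, 1.0, −0.2, 0.3)
mV — placed at fixed phase fractions of the RR interval, with widths that
scale with RR so one-beat time normalization leaves morphology invariant.
RR intervals are i.i.d. log-normal with configurable mean and coefficient
of variation, clipped to $[0.3, 2.0]$ s. A 0.05 mV, 0.3 Hz sinusoidal
baseline wander and white Gaussian noise are added. Rhythm classes map to
generator conditions: NSR (rr_cv 0.03, P waves present, noise 0.02 mV), AF
(rr_cv 0.25, P amplitude 0, the two canonical AF signatures), OTHER
(bigeminy-like alternation of short and long cycles, ±30%), NOISY
(noise-only at 0.3 mV, which buries the QRS). Heart rates are drawn
per record from 55–90 bpm (70–110 bpm for AF).

This generator gives analytically known R-peak times, RR statistics and
class structure — exactly what is needed to verify detection tolerances,
pace recovery and class separation. It does *not* reproduce real ECG:
there is no dynamical heart model, no ectopy, no muscle or electrode
artefact structure (noise is white), no QRS morphology variability within
a record, and the AF classes are separable by construction. Passing tests
therefore demonstrate that the machinery is correct and that the method
recovers planted structure; they say nothing about clinical performance,
which in the source literature requires the PhysioNet corpora and
full-scale training.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen to finish in
minutes on one CPU: 2,000 heartbeats and 30 training epochs for pace
recovery at a fixed 75 bpm, 100 records (50 clean, 50 noise-only) for the
anomaly score, and 200 NSR/AF records with 10-fold cross-validation for the
end-to-end task. Degenerate inputs are handled explicitly: records shorter
than 2 s are rejected by the detector, zero detections produce an empty
peak list rather than an error, records with fewer than two peaks yield an
empty beat list with a warning, and records from which no beat can be
extracted receive the dataset's maximum noise score (most anomalous). The
interchange format prints doubles with 17 significant digits, which
round-trips 64-bit values bit-exactly.

## Known limitations

* The trajectory model assumes one frequency per slice; signals whose rate
  changes within a slice are systematically mis-fit (the motivation for
  slicing finely in the first place).
* Mean aggregation of $\tau$ (DHB) averages a phase-periodic quantity; with
  unaligned slices the mean shift is close to meaningless, and only overall
  fidelity to plain averaging justifies including it.
* The LSTM aggregator needs enough labeled records to train; at very small
  dataset sizes the mean aggregate with an MLP head is the more reliable
  configuration.
* WFDB support covers header/signal formats 16 and 212 and MIT-format
  annotations — the PhysioNet AF corpora — not the full format zoo.
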