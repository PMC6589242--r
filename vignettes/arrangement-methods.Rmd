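---
title: "Input arrangements of resting-state EEG for CNN subject identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Input arrangements of resting-state EEG for CNN subject identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

EEG is a usable biometric: resting-state recordings carry stable,
subject-specific structure, and a classifier trained on short segments can
assign an unseen segment to the right enrolled subject. This package
implements a systematic comparison of **how the raw multichannel signal is
arranged before it is handed to a fixed shallow convolutional network**.
Six encodings of a one-second, 64-channel, 160 Hz segment are compared:

| kind | content |
|------|---------|
| M1 | amplitude-versus-time matrix, $M_1(i,t) = x_i(t)$ |
| M2 | instantaneous-energy matrix, $M_2(i,t) = H(x_i(t))^2$ |
| M3 | M1 with rows permuted by a correlation-derived channel order |
| I1/I2/I3 | the matching matrix min–max scaled to 8-bit integers |

All six are $64 \times 160$; the classifier, the optimizer and the data
split are held fixed, so any performance difference is attributable to the
arrangement alone.

## The arrangements

**Energy (M2).** The discrete Hilbert transform $H(x)$ is computed with the
standard FFT analytic-signal construction: zero the negative-frequency
bins, keep DC and Nyquist, double the rest, inverse-transform, take the
imaginary part. The continuous principal-value integral has no unique
discrete prescription; the spectral construction is the standard
realization, and the test suite pins it against an independent $O(n^2)$
circular convolution with the closed-form kernel
$h_k = (2/n)\cot(\pi k/n)$ (odd $k$). The energy is the *squared
quadrature* $H(x)^2$ — taken literally from the defining formula even
though the conventional instantaneous power would be
$|x + iH(x)|^2$; because the two definitions genuinely conflict, the
conventional form is available as `energy = "analytic_magnitude"` and the
literal form is the default.

**Channel reordering (M3).** Pairwise Pearson correlations between
channels are computed once on the pooled training-split samples of all
subjects (channel-wise concatenation), then a greedy chain is built: start
from the first channel of the default montage order, repeatedly append the
unplaced channel most correlated (largest signed coefficient) with the
most recently placed one, ties broken toward the lowest channel index.
Three points here are deliberate design choices rather than forced:

* *Global, not per-subject, order.* A per-subject order would make row
  identity itself encode the subject and leak the label trivially. The
  order is computed once per fold from training data only and applied to
  every segment.
* *Signed correlation* ("most correlated" read as the largest
  coefficient, not the largest magnitude).
* *Chain start* at the first channel of the default order (Fc5).

**Images (I1–I3).** $I(i,t) = \mathrm{round}\big((m(i,t) - m_{\min}) /
(m_{\max} - m_{\min}) \cdot 255\big)$ with min/max taken over that single
matrix — per-segment scaling, so every non-constant image attains both 0
and 255 and the encoding is invariant to affine transforms of its input.
Rounding is half-away-from-zero, stated explicitly because the affine map
alone does not determine it. A constant matrix is degenerate and yields an
all-zero image with a warning. Images are persisted as lossless 8-bit
grayscale PNG (64 px tall, 160 px wide, row = channel).

## The classifier

The network is intentionally small and fixed:

```
input 64x160x1
conv 6 @ 5x5 (valid)      -> 60x156x6   [+ batch norm]
avg-pool 2x2, stride 2    -> 30x78x6
conv 6 @ 5x5 (valid)      -> 26x74x6    [+ batch norm]
avg-pool 2x2, stride 2    -> 13x37x6
flatten                   -> 2886
dense + softmax           -> n_classes
```

Valid convolutions with stride 1 and non-overlapping average pooling are
forced by this printed shape chain. Training uses categorical
cross-entropy (the natural pairing with softmax), SGD with momentum 0.9,
constant learning rate 0.001, L2 weight decay 0.0005 on convolution and
dense weights, 30 epochs, and a mini-batch of 100 for a single-condition
dataset or 200 for the combined one (equal updates per epoch either way).
Weights are Glorot-uniform, seeded; biases start at zero. Everything —
initialization, shuffling, label permutation — derives from one integer
seed, and two runs with the same seed give identical histories.

Batch normalization is optional and sits between each convolution and its
pooling layer: $\hat x = (x - \mu_\beta)/\sqrt{\sigma^2 + \epsilon}$,
$z = \gamma \hat x + \beta$, with per-channel statistics over the
mini-batch during training, and *stored full-training-set statistics* at
inference, so predictions are invariant to how inputs are batched. The
published hyperparameter table couples "L2" with batch normalization in a
way that is not interpretable as stated; it is implemented here as
standard batch normalization with $\epsilon = 10^{-5}$ plus the
separately listed L2 weight decay. The dense stage is a single layer
straight to softmax; nothing in the architecture description recovers a
hidden layer.

Note a structural property that matters later: with average pooling and no
activation function between layers, the whole network up to the softmax is
**affine in its input**. It can only exploit subject differences that are
visible to a linear map.

There is no deep-learning framework in the package's dependency stack;
convolution and pooling forward/backward passes are compiled
(im2col + GEMM in RcppArmadillo, `src/`), the rest of the network and the
optimizer are plain R, and the gradients are verified against finite
differences in the test suite.

## Split and cross-validation protocol

Each 60 s recording is cut into 60 one-second segments. Per
subject-condition, 25 segments train, 5 validate, 30 test. The threefold
protocol is reconciled with this fixed 25/5/30 split by *index rotation*:
fold $f$ rotates the 60-index sequence by $20f$ positions before taking
the first 25 / next 5 / last 30. Within a fold the three sets are disjoint
by construction; across folds indices are necessarily reused, as any
3-fold scheme on 60 indices must. The reported accuracy
($100 \cdot C_P / N_P$) is the mean over folds. With 109 subjects this
yields exactly 2725/545/3270 inputs for a single condition and
5450/1090/6540 for both combined. No multiple-comparison adjustment is
applied anywhere; the report prints raw accuracies, to two decimals.

## The synthetic cohort generator

The generator replaces the public 109-subject recordings so that every
stage is exercisable offline. Each subject receives:

* **band gains**: a $64 \times 4$ matrix of per-channel amplitude weights
  for delta (1–4 Hz), theta (4–8 Hz), alpha (8–13 Hz) and beta
  (13–30 Hz), lognormal variation (sd 0.35 on the log scale) around base
  amplitudes 1.0 / 0.6 / 0.8 / 0.4 — a falling resting-state spectrum
  with an alpha bump, in arbitrary units of order one;
* **an eyes-closed alpha boost** drawn uniformly from [1.5, 3], applied
  multiplicatively to the alpha gain under REC — the classic posterior
  alpha increase, and the only difference between a subject's two
  conditions;
* **per-channel baseline offsets**, N(0, 2) in signal units, constant
  across time and conditions;
* **broadband white noise**, sd 0.5.

Signals are sums of band-limited sinusoids — two oscillators per channel
per band, frequency uniform within the band, phase uniform — plus the
offset and the noise. Two spectral lines per band are enough to carry the
gain fingerprint while keeping 60 s × 64-channel synthesis fast.
Oscillator draws and noise are seeded per subject (`seed + subject_id`),
so growing a cohort never changes existing subjects, and the REC/REO pair
of a subject shares oscillators and noise exactly — the alpha contrast is
therefore strict on every channel.

The baseline offsets deserve a comment, because they are the feature the
*affine* network actually uses. Raw, unreferenced, unfiltered EEG — which
is what this pipeline feeds to the network, by design — carries large
subject- and electrode-specific DC offsets from electrode/amplifier
chemistry; no detrending, re-referencing or high-pass filtering ever
removes them here. A generator with band-power fingerprints alone would be
identifiable to a spectral classifier but *invisible* to an affine one
(the oscillators are zero-mean), and indeed produces chance-level CNN
accuracy; the offsets restore the linearly accessible identity cue that
raw recordings possess. The spectral structure is kept regardless: it is
what the energy arrangement, the alpha REC/REO contrast and the
band-power sanity classifier operate on.

What the generator does **not** emulate: artifacts (blinks, EMG),
electrode drift over time, volume conduction / realistic inter-channel
correlation structure, or 1/f broadband background. Consequently, passing
tests show the pipeline's operations and protocol are correct and that
identifiable structure is recovered — they do not certify the published
accuracy ranking of the six arrangements on real recordings, and the
package deliberately asserts nothing about that ranking on synthetic data
(in particular, the penalty the reordered arrangements suffer on real
data depends on correlation structure the generator does not model).

## Numerical and degenerate-input conventions

* Channels are rows (64), time is columns (160); segment indices are
  0-based in metadata, R's own indices 1-based.
* Image quantization rounds half away from zero; re-imaging an
  already-quantized 0–255 matrix is the identity.
* A constant series has no defined Pearson correlation: `NA` with a
  warning, and undefined entries of a correlation matrix fall back to 0
  before reordering.
* Batch normalization refuses training batches of size 1; variance is the
  population (1/n) form.
* A learning rate of 0 provably leaves parameters at initialization.
* Determinism is asserted bit-for-bit on one platform/BLAS; across
  platforms floating-point reductions may differ in the last bits.

## Problem sizes used by the checks

The packaged checks run the full 109-subject cohort only for the
segmentation/split counting (no training); training-based checks use a
10-subject cohort (M1, REC+REO, 30 epochs, threefold — about 100 subjects'
worth of compute would add nothing to the property being checked, which is
recovery well above the 10% chance floor together with a label-permutation
null at chance), and unit tests use 2–4 subjects with shortened
recordings. `scripts/acceptance.R` recomputes the same quantities from
scratch at those sizes.

## Limitations

* The literal squared-quadrature energy is kept as the default even
  though instantaneous power is the conventional quantity; switch with
  `energy = "analytic_magnitude"`.
* Whether the published comparison tables were produced with or without
  batch normalization is not recoverable; both settings are first-class
  here (`use_batchnorm`).
* The EDF reader/writer is a minimal implementation sufficient for the
  64-channel, 160 Hz baseline-run layout; it is optional and nothing else
  depends on it.
* The affine network is a faithful rendering of the published
  architecture, not a recommendation: adding nonlinearities would change
  what signal structure is learnable and is out of scope.
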