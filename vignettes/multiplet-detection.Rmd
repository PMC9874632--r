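---
title: "Detecting and classifying multiplet regions in 1D 1H NMR spectra"
author: "nmrmultiplet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying multiplet regions in 1D 1H NMR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A one-dimensional proton NMR spectrum is a vector of intensities on a
frequency axis. Its information content lives in *multiplets*: groups of
peaks produced by scalar coupling, whose pattern (singlet, doublet, ...,
septet), position (chemical shift) and peak spacing (coupling constant J)
fingerprint the molecule. Annotating which stretches of the spectrum belong
to which multiplet class is routine expert work; `nmrmultiplet` automates it
as *point-wise sequence labeling*: every spectral point receives a label in
`{0, 1, ..., 7}` — 0 for baseline, k for a k-peak first-order multiplet.

The package contains the three parts such a system needs:

1. a **simulator** that renders labeled synthetic spectrum segments, used
   both as a training-data factory and as a test-fixture generator;
2. a **classifier** — an inception-style 1D convolution bank feeding a
   bidirectional LSTM and a dense stack, trained per point with categorical
   cross-entropy by a reverse-mode engine implemented in RcppArmadillo;
3. an **evaluation suite** at two granularities: per point
   (confusion-matrix metrics) and per region (confidence-ranked
   precision–recall and average precision under 1D
   intersection-over-union matching), plus a peak-level protocol for
   expert-annotated experimental spectra.

## The simulator

Segments default to 1,024 points spanning 0.512 ppm at 400 MHz — a grid
density of 5 points per Hz. Peaks are pseudo-Voigt,

$$V(\omega - \omega_0) = l_s\,G(\omega - \omega_0; \sigma)
  + (1 - l_s)\,L(\omega - \omega_0; \gamma),$$

a unit-height mixture of a Gaussian and a Lorentzian that share one
half-width at half-maximum, which forces
$\sigma = \gamma / \sqrt{2 \ln 2}$. (The HWHM identity only holds when
$\sigma$ is a standard deviation, which is how it is implemented.) Exactly
at one HWHM both components equal 0.5, for every mixing weight — a useful
invariant that the tests exercise.

A multiplet of class $n$ has peaks at
$\omega_0 + (k - (n-1)/2)J$, $k = 0..n{-}1$, with Pascal's-triangle
amplitude ratios $\binom{n-1}{k}$ and an optional linear "rooftop" tilt
mimicking strong-coupling asymmetry. The sampling ranges follow the
training-set protocol: $\gamma \in [0.5, 7]$ Hz, $l_s \in [0, 1]$,
$J/\mathrm{FWHM} \in [0.5, 18]$, signal-to-noise
$\in [10^{1/2}, 10^{5/2}]$ (log-uniform; SNR is defined as tallest peak
height over noise standard deviation, the common NMR convention),
log-uniform amplitudes over three decades, and a region count following a
truncated geometric law $P(n) \propto r^n$ with $r = 0.5$ on $1..8$ — the
simplest law consistent with an exponentially decaying region count that
still guarantees at least one signal.

Choices the protocol leaves open, decided here once:

* **Label extent.** The ground-truth label interval runs from the
  outermost peak centers outward by `labelExtentFactor` (default 2) times
  the FWHM, approximating the visually annotated extent of a resonance.
* **Placement.** Multiplets are placed by rejection sampling so that label
  intervals stay disjoint with at least one baseline point between them
  (overlapping multiplets are out of scope). When a draw cannot be placed,
  the geometric parameters $(\gamma, J/\mathrm{FWHM})$ are redrawn *with
  the class kept fixed*; only if that also fails is the region dropped.
  Keeping the class fixed preserves the uniform class composition that the
  protocol promises (wide septets would otherwise be dropped more often
  than singlets). Feasible positions are enumerated on a half-grid-step
  lattice, so a region is only ever dropped when no gap can hold even its
  narrowest admissible shape. One visible consequence of the finite
  segment: the extents of the wide classes truncate at the usable sweep,
  so per-class point-label mass grows with the number of peaks as a trend
  but nearly saturates for quintets through septets.
* **Distortions.** Zero- and first-order phase errors are each uniform in
  $[-5^\circ, +5^\circ]$; phased peaks are rendered as
  $\cos\varphi \cdot \mathrm{absorption} + \sin\varphi \cdot
  \mathrm{dispersion}$, with the Lorentzian dispersion in closed form and
  the Gaussian dispersion via Dawson's function (its exact Hilbert pair) —
  a grid-free alternative to an FFT Hilbert transform, which the test suite
  keeps as an independent oracle. Baseline distortion is a random
  polynomial of degree at most 3, capped at 2% of the tallest peak. All
  caps are configurable.
* **Intervals** are 1-based inclusive point-index pairs, the natural R
  convention; intersection-over-union counts grid points, so the
  convention does not affect any metric.

What the simulator does **not** emulate: overlapping multiplets,
higher-order patterns with several coupling constants (dd, ddd, ...),
solvent peaks, t1 noise, and field-dependent lineshape asymmetries. Tests
passing on synthetic data therefore bound implementation correctness, not
real-spectrum performance; generalization to experimental spectra must be
assessed on expert-annotated peak lists via `peakLevelConfusion()`.

## The classifier

`networkConfig()` describes the architecture: parallel 1D convolutions
with kernel sizes 4, 16, 64 and 256 (16 filters each, ELU) read the raw
normalized spectrum at four length scales; a time-distributed dense layer
(64 units, ELU) mixes the 64 concatenated channels; a bidirectional LSTM
(256 units per direction) propagates evidence along the frequency axis in
both directions, making the prediction independent of where a multiplet
sits; a decreasing time-distributed dense stack (512, 454, 136, 8; ReLU
between layers) maps each point to softmax probabilities over the 8
classes. The published architecture totals 1,225,606 trainable weights;
the two interior stack widths are not printed in the source description,
so they were solved from that total with the outer sizes fixed —
`countParameters(networkConfig())` reproduces it exactly.

Training minimizes per-point categorical cross-entropy with Adam
(learning rate $10^{-3}$ by default, batch 64, 33 epochs in the full
protocol). Weights initialize Glorot-uniform, recurrent kernels
orthogonally (one orthogonal block per gate), LSTM forget-gate biases at
1. Optional global gradient-norm clipping (default 1) and per-class loss
weights (default off, matching the reference protocol, which did not
correct the class imbalance) and a per-epoch learning-rate decay factor
are exposed in `trainingConfig()`. Inputs are normalized per segment;
the default convention is z-scoring (subtract the mean, divide by the
standard deviation), which in side-by-side runs trained markedly faster
than max-abs division — max-abs remains available, and the convention tag
travels with the model file so training and prediction always agree.

Prediction is a single full-length forward pass — the architecture is
length-agnostic — followed by a per-point argmax with ties broken toward
the lowest class index. Spectra on other grids are first brought to the
training density (5 points per Hz) by `resampleSpectrum()`, whose
back-map lets labels be reported on the original grid. `majorityFilter()`
(windowed mode, ties keep the original label) is available as
post-processing against fragmented label runs.

### The training engine

No deep-learning framework is involved: forward and reverse-mode passes
for the convolution bank, the BiLSTM (full backpropagation through time)
and the dense stack, plus the Adam update, are implemented in
RcppArmadillo (`src/nn.cpp`). The test suite verifies the gradients
against central finite differences on a small configuration to $10^{-4}$
relative tolerance — the property that separates a correct engine from a
subtly broken one.

## Evaluation

**Point-wise.** `pointwiseConfusion()` counts (true, predicted) label
pairs; `classMetrics()` derives one-vs-rest TP/FP/FN/TN, accuracy,
precision, recall and F1 per class. Ratios with empty denominators are
reported as `NA`, never as 0.

**Object-wise.** A *label prediction* is a maximal run of identically
labeled nonzero points; its confidence is the mean softmax probability of
its own class over the run. Predictions are ranked by confidence and
matched greedily one-to-one to ground-truth regions of the same class; a
prediction is a true positive when its point-count IOU reaches the
threshold $t$ (0.50 and 0.75 by default; "reaches" means $\ge t$).
Average precision uses all-point interpolation,
$AP = \sum_n (R_{n+1} - R_n)\,\max_{\tilde R \ge R_{n+1}} P(\tilde R)$,
and mAP averages classes with at least one ground-truth region. The
recall denominator is the number of ground-truth regions — the standard
convention; the alternative reading (total predictions, under which the
final precision and recall coincide) is selectable via
`recallDenominator = "predictions"`. Object-wise metrics punish
*fragmentation* — a region split across classes scores near-zero AP while
barely moving point-wise accuracy — which is exactly why both levels are
reported.

**Peak-level.** For experimental spectra annotated as peak lists
(position ppm, amplitude, line width, class), each peak is looked up at
its nearest grid point of the prediction; a baseline label there counts
as "unassigned" rather than misclassified, giving a 7×8 confusion matrix.

## Problem sizes used by the shipped checks

The full protocol (100,000 segments, 33 epochs, 10,000 test segments) is
reproduced by `scripts/full_protocol.R` and takes many hours on a single
CPU. The package's own checks run a deliberately scaled-down study:

* simulator properties are asserted on 10,000 generated segments;
* learning sanity trains a reduced network of the same architecture
  family (kernels 4/16/64/256 with 16 filters, 64-unit dense mixer,
  48-unit BiLSTM per direction, stack 128–64–32–8) on 2,000 easy-mode
  segments of 512 points for 10 epochs, with 400 independently generated
  segments held out — easy mode means SNR at least $10^{1.5}$,
  $J/\mathrm{FWHM} \ge 4$, no phase or baseline distortion, and one
  decade of amplitude range (with SNR tied to the tallest peak, a
  three-decade range would put some multiplets far below the noise floor
  and make their labels unlearnable in principle — a detectability
  argument, not a tuning choice);
* the pipeline layout (75/25 split, independent test set) is exercised at
  a small `scale` with the same code path that runs the full protocol at
  `scale = 1`.

## Known limitations

* Only non-overlapping first-order multiplets of 1–7 peaks are modeled;
  anything else in a real spectrum will be labeled with whatever class
  the network finds closest, or baseline.
* The simulator's distortion magnitudes stand in for unpublished
  experimental settings; they are configurable but their defaults are
  package choices.
* The training engine favors clarity over throughput: it is single
  threaded on top of BLAS and trains the full protocol orders of
  magnitude slower than a GPU framework would.
* Real-spectrum ingestion is limited to exported two-column tables;
  vendor formats are intentionally out of scope.
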