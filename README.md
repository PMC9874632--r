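# nmrmultiplet

Automatic detection and classification of multiplet signal regions in
one-dimensional ¹H NMR spectra.

A ¹H NMR spectrum encodes molecular structure in its *multiplets* — groups
of peaks split by scalar coupling. `nmrmultiplet` labels every point of a
spectrum with one of eight classes (0 = baseline, 1–7 = singlet … septet),
the way an expert annotates signal regions, using a neural sequence
labeler trained entirely on simulated spectra. The package is aimed at
spectroscopists and methods developers who need reproducible, quantitative
multiplet annotation or a controlled benchmark for it.

It provides three tightly coupled components:

* **Simulator** — labeled synthetic segments built from pseudo-Voigt peaks
  `V(x) = ls·G(x; σ) + (1−ls)·L(x; γ)` (shared HWHM, so `σ = γ/√(2 ln 2)`),
  binomial multiplet amplitude ratios with a rooftop tilt, phase and
  baseline distortions, and Gaussian noise at a controlled
  signal-to-noise ratio. Defaults: 1,024 points over 0.512 ppm at 400 MHz
  (5 points/Hz), γ ∈ [0.5, 7] Hz, J/FWHM ∈ [0.5, 18], SNR ∈ [10^½, 10^2.5],
  exponentially decaying region counts, non-overlapping regions.
* **Classifier** — parallel Conv1D branches (kernels 4/16/64/256, 16
  filters each, ELU) → time-distributed dense (64, ELU) → bidirectional
  LSTM (256/direction) → dense stack 512–454–136–8 (ReLU) → per-point
  softmax; 1,225,606 trainable weights. Forward, full reverse-mode
  gradients (including backpropagation through time) and Adam are
  implemented in RcppArmadillo — no deep-learning framework is required.
* **Evaluation** — point-wise confusion-matrix metrics (accuracy,
  precision, recall, F1 per class), object-wise confidence-ranked
  precision–recall with 1D intersection-over-union matching and all-point
  interpolated average precision (AP50/AP75, mAP), and a peak-level
  protocol for expert-annotated experimental spectra.

## Worked example

```r
library(nmrmultiplet)

# simulate a labeled segment and look at its ground truth
seg <- generateSegment(simulationConfig(), seed = 7)
seg
#> SpectrumSegment: 1024 points, 204.8 Hz sweep at 400 MHz, 6 signal region(s)
labelIntervals(seg)
#>   class start  end
#> 1     3   354  446
#> 2     6   676 1021
#> 3     7     7  302
#> 4     2   448  637
#> 5     3   326  351
#> 6     3   649  673

# the reference architecture
net <- buildNetwork(networkConfig(), seed = 1)
net
#> MultipletClassifier (untrained): 1,225,606 trainable parameters
#>   conv kernels 4/16/64/256 x 16 filters | dense 64 | BiLSTM 256/dir | stack 512-454-136-8
```

A desk-scale version of the whole protocol (simulate → train → predict →
evaluate) runs through one call; `scale` shrinks the full 100,000-segment /
33-epoch experiment proportionally:

```r
res <- runPipeline("run1", scale = 0.02, seed = 1,
                   simConfig = easySimulationConfig(nPoints = 512L),
                   netConfig  = networkConfig(convKernels = c(4L, 16L, 64L, 256L),
                                              convFilters = 16L,
                                              postConvDenseUnits = 64L,
                                              lstmUnits = 48L,
                                              denseStack = c(128L, 64L, 32L, 8L)))
res$results$metrics          # per-class A/P/R/F1
res$results$objectwise$iou50$mAP
```

`run1/` then contains the trained model, per-epoch history, the pooled
confusion matrix, a JSON metrics report, and a manifest with every seed
and file digest needed to reproduce the run. The full-scale experiment is
`scripts/full_protocol.R` (hours on one CPU).

A shell interface with the same verbs is installed at
`system.file("exec", "nmrmultiplet", package = "nmrmultiplet")`:
`simulate`, `train`, `predict` (TSV spectrum in, TSV labels out, optional
`--majority-window`), `evaluate`, `pipeline`.

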