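#' @import methods
NULL

# ---------------------------------------------------------------------------
# Simulation configuration
# ---------------------------------------------------------------------------

#' Simulation configuration for synthetic spectrum segments
#'
#' Holds every tunable of the synthetic-spectrum generator: grid geometry,
#' lineshape and coupling ranges, noise, and distortion caps. The defaults
#' reproduce the training-set protocol: 1,024-point segments over 0.512 ppm
#' at 400 MHz (5 points per Hz), Lorentzian half-widths between 0.5 and
#' 7 Hz, J/FWHM ratios between 0.5 and 18, and signal-to-noise ratios
#' between 10^0.5 and 10^2.5.
#'
#' @slot nPoints number of points per segment.
#' @slot sweepPpm spectral width of a segment, ppm.
#' @slot baseFrequencyMHz spectrometer base frequency, MHz.
#' @slot gammaRange Lorentzian half-width at half-maximum range, Hz.
#' @slot lsRange pseudo-Voigt Gaussian mixing weight range (0 = Lorentzian,
#'   1 = Gaussian).
#' @slot ratioRange range of J / FWHM (peak separation over line width).
#' @slot snrRange signal-to-noise range; SNR is defined as tallest peak
#'   height over the noise standard deviation.
#' @slot amplitudeRange multiplet amplitude range; amplitudes are sampled
#'   log-uniformly.
#' @slot regionDecay ratio of the truncated geometric law for the number of
#'   signal regions per segment.
#' @slot maxRegions upper truncation of the region count.
#' @slot rooftopMax maximum absolute rooftop tilt.
#' @slot phaseMaxDeg cap on zero- and first-order phase errors, degrees.
#' @slot baselineDegree maximum degree of the random baseline polynomial.
#' @slot baselineMaxFrac baseline cap as a fraction of the tallest peak.
#' @slot labelExtentFactor label regions extend this many FWHM beyond the
#'   outermost peak centers.
#' @slot seed default random seed used when none is supplied.
#' @export
setClass("SimulationConfig", representation(
  nPoints = "integer", sweepPpm = "numeric", baseFrequencyMHz = "numeric",
  gammaRange = "numeric", lsRange = "numeric", ratioRange = "numeric",
  snrRange = "numeric", amplitudeRange = "numeric",
  regionDecay = "numeric", maxRegions = "integer",
  rooftopMax = "numeric", phaseMaxDeg = "numeric",
  baselineDegree = "integer", baselineMaxFrac = "numeric",
  labelExtentFactor = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  rng2 <- function(r, name, degenerate_ok = FALSE) {
    if (length(r) != 2 || any(!is.finite(r)) || r[2] < r[1] ||
        (!degenerate_ok && r[2] <= r[1]))
      msg <<- c(msg, sprintf("'%s' must be a non-degenerate range", name))
  }
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  rng2(object@gammaRange, "gammaRange")
  rng2(object@lsRange, "lsRange", degenerate_ok = TRUE)
  rng2(object@ratioRange, "ratioRange")
  rng2(object@snrRange, "snrRange")
  rng2(object@amplitudeRange, "amplitudeRange")
  if (any(object@gammaRange <= 0)) msg <- c(msg, "gammaRange must be positive")
  if (object@regionDecay <= 0 || object@regionDecay >= 1)
    msg <- c(msg, "regionDecay must lie in (0, 1)")
  if (object@maxRegions < 1L) msg <- c(msg, "maxRegions must be >= 1")
  if (object@labelExtentFactor <= 0)
    msg <- c(msg, "labelExtentFactor must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param nPoints points per segment (default 1024).
#' @param sweepPpm segment width in ppm (default 0.512).
#' @param baseFrequencyMHz spectrometer frequency in MHz (default 400).
#' @param gammaRange,lsRange,ratioRange,snrRange,amplitudeRange sampling
#'   ranges, see \linkS4class{SimulationConfig}.
#' @param regionDecay,maxRegions truncated geometric law for the number of
#'   signal regions (P(n) proportional to \code{regionDecay^n},
#'   n = 1..\code{maxRegions}).
#' @param rooftopMax,phaseMaxDeg,baselineDegree,baselineMaxFrac distortion
#'   caps.
#' @param labelExtentFactor label margin in FWHM units beyond the outermost
#'   peak centers (default 2).
#' @param seed default seed.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig()
#' cfg
#' @export
simulationConfig <- function(nPoints = 1024L, sweepPpm = 0.512,
                             baseFrequencyMHz = 400,
                             gammaRange = c(0.5, 7), lsRange = c(0, 1),
                             ratioRange = c(0.5, 18),
                             snrRange = c(10^0.5, 10^2.5),
                             amplitudeRange = c(1, 1000),
                             regionDecay = 0.5, maxRegions = 8L,
                             rooftopMax = 0.2, phaseMaxDeg = 5,
                             baselineDegree = 3L, baselineMaxFrac = 0.02,
                             labelExtentFactor = 2, seed = 1L) {
  new("SimulationConfig", nPoints = as.integer(nPoints), sweepPpm = sweepPpm,
      baseFrequencyMHz = baseFrequencyMHz, gammaRange = gammaRange,
      lsRange = lsRange, ratioRange = ratioRange, snrRange = snrRange,
      amplitudeRange = amplitudeRange, regionDecay = regionDecay,
      maxRegions = as.integer(maxRegions), rooftopMax = rooftopMax,
      phaseMaxDeg = phaseMaxDeg, baselineDegree = as.integer(baselineDegree),
      baselineMaxFrac = baselineMaxFrac,
      labelExtentFactor = labelExtentFactor, seed = as.integer(seed))
}

#' Easy-mode simulation configuration
#'
#' A benign regime used for learning-sanity checks: high signal-to-noise
#' (at least 10^1.5), well-resolved multiplets (J/FWHM at least 4), no phase
#' or baseline distortion, and a single decade of amplitude dynamic range so
#' that every multiplet stays well above the noise floor.
#'
#' @param nPoints points per segment; the sweep width scales with it so the
#'   grid density stays at the training default of 5 points per Hz.
#' @param ... further arguments passed to [simulationConfig()].
#' @return A \linkS4class{SimulationConfig}.
#' @export
easySimulationConfig <- function(nPoints = 1024L, ...) {
  simulationConfig(nPoints = nPoints,
                   sweepPpm = 0.512 * as.integer(nPoints) / 1024,
                   snrRange = c(10^1.5, 10^2.5), ratioRange = c(4, 18),
                   amplitudeRange = c(100, 1000),
                   phaseMaxDeg = 0, baselineMaxFrac = 0, ...)
}

# ---------------------------------------------------------------------------
# Multiplet specification
# ---------------------------------------------------------------------------

#' One first-order multiplet resonance
#'
#' @slot classId integer 1..7; equals the number of peaks (1 = singlet,
#'   7 = septet).
#' @slot center multiplet center, Hz.
#' @slot J coupling constant (spacing between adjacent peaks), Hz.
#' @slot gamma Lorentzian half-width at half-maximum, Hz.
#' @slot lsMix pseudo-Voigt Gaussian weight in [0, 1].
#' @slot amplitude height of the tallest peak before the rooftop tilt.
#' @slot tilt rooftop amplitude tilt, dimensionless.
#' @export
setClass("MultipletSpec", representation(
  classId = "integer", center = "numeric", J = "numeric", gamma = "numeric",
  lsMix = "numeric", amplitude = "numeric", tilt = "numeric"))

setValidity("MultipletSpec", function(object) {
  msg <- character()
  if (object@classId < 1L || object@classId > 7L)
    msg <- c(msg, "classId must be in 1..7")
  if (object@gamma <= 0) msg <- c(msg, "gamma must be positive")
  if (object@lsMix < 0 || object@lsMix > 1)
    msg <- c(msg, "lsMix must lie in [0, 1]")
  if (object@J < 0) msg <- c(msg, "J must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Create a multiplet specification
#'
#' @param classId multiplet class, 1 (singlet) to 7 (septet).
#' @param center center position, Hz.
#' @param J coupling constant, Hz.
#' @param gamma Lorentzian half-width at half-maximum, Hz.
#' @param lsMix pseudo-Voigt Gaussian weight.
#' @param amplitude tallest-peak height.
#' @param tilt rooftop tilt.
#' @return A \linkS4class{MultipletSpec}.
#' @examples
#' multipletSpec(3, center = 100, J = 12, gamma = 1)
#' @export
multipletSpec <- function(classId, center, J, gamma, lsMix = 0,
                          amplitude = 1, tilt = 0) {
  new("MultipletSpec", classId = as.integer(classId), center = center,
      J = J, gamma = gamma, lsMix = lsMix, amplitude = amplitude, tilt = tilt)
}

#' Peak center positions of a multiplet
#'
#' Centers are \code{center + (k - (n - 1)/2) * J} for k = 0..n-1.
#'
#' @param spec a \linkS4class{MultipletSpec}.
#' @return Numeric vector of peak positions, Hz.
#' @export
peakCenters <- function(spec) {
  n <- spec@classId
  spec@center + (seq_len(n) - 1 - (n - 1) / 2) * spec@J
}

# ---------------------------------------------------------------------------
# Spectrum segment
# ---------------------------------------------------------------------------

#' A labeled spectrum segment
#'
#' A one-dimensional spectrum segment on an ascending uniform frequency axis
#' with per-point ground-truth labels. Label 0 marks baseline; labels 1..7
#' mark points belonging to a singlet..septet. The \code{meta} list records
#' the constituent \linkS4class{MultipletSpec}s, their label intervals, and
#' every noise/distortion draw, so a segment is fully auditable.
#'
#' @slot axis point positions, Hz, ascending.
#' @slot intensity intensity vector.
#' @slot labels integer labels in 0..7, one per point.
#' @slot sweepWidth segment width, Hz.
#' @slot baseFrequency spectrometer frequency, MHz.
#' @slot meta generation metadata (multiplets, label intervals, draws, seed).
#' @export
setClass("SpectrumSegment", representation(
  axis = "numeric", intensity = "numeric", labels = "integer",
  sweepWidth = "numeric", baseFrequency = "numeric", meta = "list"))

setValidity("SpectrumSegment", function(object) {
  msg <- character()
  n <- length(object@axis)
  if (length(object@intensity) != n || length(object@labels) != n)
    msg <- c(msg, "axis, intensity and labels must have equal length")
  if (n > 1 && any(diff(object@axis) <= 0))
    msg <- c(msg, "axis must be strictly ascending")
  if (any(object@labels < 0L | object@labels > 7L))
    msg <- c(msg, "labels must lie in 0..7")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpectrumSegment-class intensity vector accessor
#' @param object,x a \code{SpectrumSegment}.
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @export
setMethod("intensity", "SpectrumSegment", function(x) x@intensity)

#' Per-point ground-truth or predicted labels
#' @param x an object carrying per-point labels.
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))
#' @export
setMethod("pointLabels", "SpectrumSegment", function(x) x@labels)

#' Frequency axis accessor
#' @param x an object with a frequency axis.
#' @export
setGeneric("spectrumAxis", function(x) standardGeneric("spectrumAxis"))
#' @export
setMethod("spectrumAxis", "SpectrumSegment", function(x) x@axis)

#' Ground-truth label intervals of a segment
#'
#' @param x a \linkS4class{SpectrumSegment}.
#' @return data.frame with columns class, start, end (1-based, inclusive).
#' @export
labelIntervals <- function(x) {
  stopifnot(is(x, "SpectrumSegment"))
  x@meta$labelIntervals
}

setMethod("show", "SpectrumSegment", function(object) {
  nr <- nrow(object@meta$labelIntervals %||% data.frame())
  cat(sprintf(
    "SpectrumSegment: %d points, %.1f Hz sweep at %.0f MHz, %d signal region(s)\n",
    length(object@axis), object@sweepWidth, object@baseFrequency, nr))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Labeled dataset
# ---------------------------------------------------------------------------

#' A reproducible collection of labeled spectrum segments
#'
#' Segments are stored as row-per-segment intensity and label matrices plus
#' a per-segment list of ground-truth region tables. The generating
#' configuration, master seed and per-segment seeds are retained so the
#' dataset is a pure function of its provenance.
#'
#' @slot intensity numeric matrix, segments in rows.
#' @slot labels integer matrix, same shape.
#' @slot split character vector of partition tags ("train"/"validation"/...).
#' @slot regions list of per-segment data.frames (class, start, end).
#' @slot config the \linkS4class{SimulationConfig} used.
#' @slot seed master seed.
#' @slot segmentSeeds per-segment seeds derived from the master seed.
#' @export
setClass("LabeledDataset", representation(
  intensity = "matrix", labels = "matrix", split = "character",
  regions = "list", config = "SimulationConfig", seed = "integer",
  segmentSeeds = "integer"))

setValidity("LabeledDataset", function(object) {
  msg <- character()
  n <- nrow(object@intensity)
  if (!all(dim(object@labels) == dim(object@intensity)))
    msg <- c(msg, "labels and intensity must have identical shape")
  if (length(object@split) != n || length(object@regions) != n ||
      length(object@segmentSeeds) != n)
    msg <- c(msg, "split, regions and segmentSeeds must match segment count")
  if (length(msg)) msg else TRUE
})

#' @describeIn LabeledDataset-class number of segments
#' @param x a \code{LabeledDataset}.
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @export
setMethod("nSegments", "LabeledDataset", function(x) nrow(x@intensity))

#' Partition tags of a dataset
#' @param x a \linkS4class{LabeledDataset}.
#' @export
datasetSplit <- function(x) x@split

#' Materialize one segment of a dataset
#'
#' @param x a \linkS4class{LabeledDataset}.
#' @param i segment index.
#' @return The i-th segment as a \linkS4class{SpectrumSegment} (with region
#'   metadata but without the per-draw distortion record, which lives in the
#'   per-segment seed).
#' @export
getSegment <- function(x, i) {
  stopifnot(is(x, "LabeledDataset"), i >= 1, i <= nSegments(x))
  cfg <- x@config
  sweepHz <- cfg@sweepPpm * cfg@baseFrequencyMHz
  axis <- (seq_len(cfg@nPoints) - 1) * sweepHz / cfg@nPoints
  new("SpectrumSegment", axis = axis, intensity = x@intensity[i, ],
      labels = as.integer(x@labels[i, ]), sweepWidth = sweepHz,
      baseFrequency = cfg@baseFrequencyMHz,
      meta = list(labelIntervals = x@regions[[i]],
                  seed = x@segmentSeeds[i]))
}

setMethod("show", "LabeledDataset", function(object) {
  tab <- table(object@split)
  cat(sprintf("LabeledDataset: %d segments x %d points (%s), seed %d\n",
              nrow(object@intensity), ncol(object@intensity),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              object@seed))
})

# ---------------------------------------------------------------------------
# Network configuration / classifier / prediction
# ---------------------------------------------------------------------------

#' Architecture of the point-wise multiplet classifier
#'
#' An inception-style bank of parallel 1D convolutions over the raw
#' spectrum (ELU), a time-distributed dense layer (ELU), a bidirectional
#' LSTM, and a decreasing time-distributed dense stack (ReLU) ending in a
#' per-point softmax over \code{nClasses} labels. The default configuration
#' (kernels 4/16/64/256 with 16 filters each, 64 post-convolution dense
#' units, 256 LSTM units per direction, dense stack 512-454-136-8) has
#' exactly 1,225,606 trainable parameters.
#'
#' @slot convKernels kernel sizes of the parallel convolution branches.
#' @slot convFilters filters per branch.
#' @slot postConvDenseUnits units of the dense layer between the
#'   convolution bank and the LSTM.
#' @slot lstmUnits LSTM units per direction.
#' @slot denseStack sizes of the dense stack; strictly decreasing, last
#'   element equals \code{nClasses}.
#' @slot nClasses number of output classes (baseline + 7 multiplets).
#' @export
setClass("NetworkConfig", representation(
  convKernels = "integer", convFilters = "integer",
  postConvDenseUnits = "integer", lstmUnits = "integer",
  denseStack = "integer", nClasses = "integer"))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (any(object@convKernels < 1L)) msg <- c(msg, "kernel sizes must be >= 1")
  if (object@convFilters < 1L || object@postConvDenseUnits < 1L ||
      object@lstmUnits < 1L)
    msg <- c(msg, "all unit counts must be positive")
  st <- object@denseStack
  if (any(diff(st) >= 0)) msg <- c(msg, "denseStack must be strictly decreasing")
  if (st[length(st)] != object@nClasses)
    msg <- c(msg, "last denseStack element must equal nClasses")
  if (length(msg)) msg else TRUE
})

#' Create a network configuration
#'
#' @param convKernels kernel sizes of the parallel Conv1D branches.
#' @param convFilters filters per branch.
#' @param postConvDenseUnits units of the time-distributed dense layer
#'   between convolutions and LSTM.
#' @param lstmUnits LSTM units per direction.
#' @param denseStack decreasing dense-stack sizes ending at \code{nClasses}.
#' @param nClasses number of classes.
#' @return A \linkS4class{NetworkConfig}.
#' @examples
#' countParameters(networkConfig())   # 1225606
#' @export
networkConfig <- function(convKernels = c(4L, 16L, 64L, 256L),
                          convFilters = 16L, postConvDenseUnits = 64L,
                          lstmUnits = 256L,
                          denseStack = c(512L, 454L, 136L, 8L),
                          nClasses = 8L) {
  new("NetworkConfig", convKernels = as.integer(convKernels),
      convFilters = as.integer(convFilters),
      postConvDenseUnits = as.integer(postConvDenseUnits),
      lstmUnits = as.integer(lstmUnits), denseStack = as.integer(denseStack),
      nClasses = as.integer(nClasses))
}

#' A point-wise multiplet classifier
#'
#' Produced untrained by [buildNetwork()] and trained by
#' [trainClassifier()]. Prediction is deterministic given the weights and
#' the input.
#'
#' @slot config the \linkS4class{NetworkConfig}.
#' @slot weights named list of weight matrices.
#' @slot normalization input-normalization convention tag ("maxabs").
#' @slot history per-epoch training history (loss/accuracy, train and
#'   validation).
#' @slot trained logical.
#' @slot pointsPerHz grid density the classifier was trained at; inputs on
#'   other grids should be resampled to this density first.
#' @export
setClass("MultipletClassifier", representation(
  config = "NetworkConfig", weights = "list", normalization = "character",
  history = "data.frame", trained = "logical", pointsPerHz = "numeric"))

#' Training history accessor
#' @param x a \linkS4class{MultipletClassifier}.
#' @return data.frame with per-epoch loss and accuracy.
#' @export
trainingHistory <- function(x) {
  stopifnot(is(x, "MultipletClassifier"))
  x@history
}

setMethod("show", "MultipletClassifier", function(object) {
  cat(sprintf(
    "MultipletClassifier (%s): %s trainable parameters\n  conv kernels %s x %d filters | dense %d | BiLSTM %d/dir | stack %s\n",
    if (object@trained) "trained" else "untrained",
    format(countParameters(object), big.mark = ","),
    paste(object@config@convKernels, collapse = "/"),
    object@config@convFilters, object@config@postConvDenseUnits,
    object@config@lstmUnits,
    paste(object@config@denseStack, collapse = "-")))
})

#' Per-point class probabilities and labels
#'
#' @slot probabilities n_points x n_classes softmax matrix; rows lie on the
#'   simplex.
#' @slot labels integer argmax labels (ties broken toward the lowest class
#'   index).
#' @export
setClass("PredictionResult", representation(
  probabilities = "matrix", labels = "integer"))

setValidity("PredictionResult", function(object) {
  msg <- character()
  if (nrow(object@probabilities) != length(object@labels))
    msg <- c(msg, "one label per probability row required")
  if (any(abs(rowSums(object@probabilities) - 1) > 1e-5))
    msg <- c(msg, "probability rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Probability matrix accessor
#' @param x a \linkS4class{PredictionResult}.
#' @export
probabilities <- function(x) {
  stopifnot(is(x, "PredictionResult"))
  x@probabilities
}

#' @export
setMethod("pointLabels", "PredictionResult", function(x) x@labels)

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: %d points, %d classes, %d signal point(s)\n",
              nrow(object@probabilities), ncol(object@probabilities),
              sum(object@labels != 0L)))
})
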