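# Prediction, grid resampling, and the majority post-filter.

#' Predict per-point multiplet classes
#'
#' Normalizes the input with the classifier's stored convention, runs a
#' single full-length forward pass (the architecture is length-agnostic),
#' and takes the per-point argmax. Ties are broken toward the lowest class
#' index. Deterministic.
#'
#' @param object a \linkS4class{MultipletClassifier}.
#' @param newdata numeric intensity vector of length at least the largest
#'   convolution kernel.
#' @param ... ignored.
#' @return A \linkS4class{PredictionResult}.
#' @export
setMethod("predict", "MultipletClassifier", function(object, newdata, ...) {
  x <- as.numeric(newdata)
  kmax <- max(object@config@convKernels)
  if (length(x) < kmax)
    stop(sprintf("input has %d points but the largest kernel needs %d",
                 length(x), kmax))
  x <- applyNormalization(x, object@normalization)
  cube <- cpp_nn_forward(object@weights, cfgToCpp(object@config),
                         matrix(x, ncol = 1))
  probs <- cube[, , 1, drop = TRUE]
  new("PredictionResult", probabilities = probs,
      labels = argmaxLabels(probs))
})

# deterministic per-row argmax; ties break toward the lowest class index
argmaxLabels <- function(probs) {
  as.integer(max.col(probs, ties.method = "first") - 1L)
}

#' Resample a spectrum to a target grid density
#'
#' Linearly interpolates onto a uniform grid with \code{targetPointsPerHz}
#' points per Hz (the training default is 1024 points / 204.8 Hz = 5). The
#' returned back-map carries each original point to its nearest resampled
#' index, so labels predicted on the resampled grid can be reported on the
#' original one.
#'
#' @param axis strictly monotone position vector, Hz.
#' @param intensity intensity vector of the same length.
#' @param targetPointsPerHz target grid density, points per Hz.
#' @return list(axis, intensity, backMap).
#' @export
resampleSpectrum <- function(axis, intensity, targetPointsPerHz) {
  if (length(axis) != length(intensity))
    stop("axis and intensity lengths differ")
  d <- diff(axis)
  if (all(d < 0)) { axis <- rev(axis); intensity <- rev(intensity); d <- -rev(d) }
  if (any(d <= 0)) stop("axis must be strictly monotone")
  if (targetPointsPerHz <= 0) stop("target density must be positive")
  step <- 1 / targetPointsPerHz
  newAxis <- seq(axis[1], axis[length(axis)], by = step)
  newInt <- stats::approx(axis, intensity, xout = newAxis)$y
  backMap <- pmin(length(newAxis),
                  pmax(1L, as.integer(round((axis - newAxis[1]) / step)) + 1L))
  list(axis = newAxis, intensity = newInt, backMap = backMap)
}

#' Majority filter for label vectors
#'
#' Replaces each point by the modal label within its centered window
#' (windows are truncated at the edges). When the mode is tied the original
#' label is kept. A useful post-processing step against fragmented
#' predictions.
#'
#' @param labels integer label vector.
#' @param window odd window width; 1 is the identity.
#' @return Filtered label vector.
#' @examples
#' majorityFilter(c(1L, 1L, 2L, 1L, 1L), 5L)   # all 1
#' @export
majorityFilter <- function(labels, window) {
  if (length(window) != 1L || window < 1L || window %% 2L == 0L)
    stop("'window' must be an odd positive integer, got ", format(window))
  if (window == 1L) return(labels)
  n <- length(labels)
  h <- (window - 1L) %/% 2L
  out <- labels
  for (i in seq_len(n)) {
    w <- labels[max(1L, i - h):min(n, i + h)]
    counts <- table(w)
    best <- names(counts)[counts == max(counts)]
    if (length(best) == 1L) out[i] <- as.integer(best)
    # tie: keep the original label
  }
  out
}
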