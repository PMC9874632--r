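# Rendering first-order multiplets: binomial peak amplitudes, rooftop tilt,
# and the sum of pseudo-Voigt peaks with its ground-truth label interval.

#' Relative peak amplitudes of a first-order multiplet
#'
#' First-order multiplets carry Pascal's-triangle intensity ratios: the
#' amplitudes are the binomial coefficients C(n-1, k), k = 0..n-1,
#' normalized so the tallest peak has height 1.
#'
#' @param nPeaks number of peaks (multiplet class), 1..7.
#' @return Numeric vector of length \code{nPeaks} with maximum 1.
#' @examples
#' binomialAmplitudes(3)   # c(0.5, 1, 0.5)
#' @export
binomialAmplitudes <- function(nPeaks) {
  if (length(nPeaks) != 1L || is.na(nPeaks) || nPeaks != round(nPeaks) ||
      nPeaks < 1 || nPeaks > 7)
    stop("'nPeaks' must be an integer in 1..7, got ", format(nPeaks))
  a <- choose(nPeaks - 1, seq_len(nPeaks) - 1)
  a / max(a)
}

#' Apply a rooftop tilt to multiplet peak amplitudes
#'
#' Mimics the rooftop effect of strong coupling by tilting the amplitudes
#' linearly across the multiplet: peak k of n is scaled by
#' \code{1 + tilt * (2k - (n - 1)) / (n - 1)} (k = 0..n-1). A singlet has no
#' tilt axis and is returned unchanged.
#'
#' @param amplitudes peak amplitude vector.
#' @param tilt dimensionless tilt; zero is the identity.
#' @return Tilted amplitudes; an error is raised if any amplitude would
#'   become non-positive.
#' @examples
#' applyRooftop(c(1, 1), 0.2)   # c(0.8, 1.2)
#' @export
applyRooftop <- function(amplitudes, tilt) {
  n <- length(amplitudes)
  if (n == 1L) return(amplitudes)
  k <- seq_len(n) - 1
  out <- amplitudes * (1 + tilt * (2 * k - (n - 1)) / (n - 1))
  if (any(out <= 0))
    stop("rooftop tilt ", format(tilt), " produces non-positive amplitudes")
  out
}

#' Render one multiplet onto a frequency axis
#'
#' Sums \code{classId} pseudo-Voigt peaks at centers
#' \code{center + (k - (n-1)/2) * J}, with binomial amplitude ratios,
#' rooftop tilt, and overall scale \code{amplitude}. The ground-truth label
#' interval extends \code{labelExtentFactor} FWHM (= 2 gamma) beyond the
#' outermost peak centers and is returned as 1-based inclusive point
#' indices.
#'
#' @param spec a \linkS4class{MultipletSpec}.
#' @param axis ascending frequency axis, Hz.
#' @param labelExtentFactor label margin in FWHM units (default 2).
#' @param mode "absorption" for the usual lineshape, "dispersion" for its
#'   dispersion-mode partner (used for phase distortion).
#' @return list with \code{intensity} (length of \code{axis}),
#'   \code{start}, \code{end} (label interval, 1-based inclusive).
#' @examples
#' cfg <- simulationConfig()
#' ax <- seq(0, 204.8, length.out = 1024)
#' r <- renderMultiplet(multipletSpec(3, 100, 10, 0.5), ax)
#' @export
renderMultiplet <- function(spec, axis, labelExtentFactor = 2,
                            mode = c("absorption", "dispersion")) {
  mode <- match.arg(mode)
  stopifnot(is(spec, "MultipletSpec"))
  centers <- peakCenters(spec)
  lo <- min(centers) - labelExtentFactor * 2 * spec@gamma
  hi <- max(centers) + labelExtentFactor * 2 * spec@gamma
  tol <- 1e-9 * max(1, abs(axis[length(axis)]))
  if (lo < axis[1] - tol || hi > axis[length(axis)] + tol)
    stop(sprintf(
      "multiplet label interval [%.2f, %.2f] Hz falls outside the axis [%.2f, %.2f]",
      lo, hi, axis[1], axis[length(axis)]))
  heights <- spec@amplitude * applyRooftop(binomialAmplitudes(spec@classId),
                                           spec@tilt)
  shape <- if (mode == "absorption") pseudoVoigt else pseudoVoigtDispersion
  y <- numeric(length(axis))
  for (k in seq_along(centers))
    y <- y + heights[k] * shape(axis - centers[k], spec@gamma, spec@lsMix)
  idx <- which(axis >= lo & axis <= hi)
  list(intensity = y, start = min(idx), end = max(idx))
}
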