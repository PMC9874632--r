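# Segment-level simulation: distortions, noise, and the generator that
# assembles labeled segments from randomly drawn multiplets.

#' Add Gaussian noise at a given signal-to-noise ratio
#'
#' The noise standard deviation is (tallest peak height) / snr, the common
#' NMR convention. Labels are unchanged. Uses the current R random stream;
#' call \code{set.seed()} beforehand for reproducibility.
#'
#' @param segment a \linkS4class{SpectrumSegment} with noiseless intensity.
#' @param snr signal-to-noise ratio; \code{Inf} returns the segment
#'   unchanged.
#' @return The segment with noise added and the draw recorded in its meta.
#' @export
addNoise <- function(segment, snr) {
  stopifnot(is(segment, "SpectrumSegment"))
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("'snr' must be a single positive number")
  if (is.infinite(snr)) return(segment)
  peak <- max(abs(segment@intensity))
  if (peak == 0)
    stop("SNR is undefined for an all-zero segment")
  sd <- peak / snr
  segment@intensity <- segment@intensity + stats::rnorm(length(segment@intensity), 0, sd)
  segment@meta$snr <- snr
  segment@meta$noiseSd <- sd
  segment@meta$noiseAdded <- TRUE
  segment
}

#' Apply zero- and first-order phase distortion
#'
#' Re-renders every multiplet as
#' \code{cos(phi) * absorption + sin(phi) * dispersion}, where the phase
#' \code{phi} varies linearly from \code{theta0} at the segment start to
#' \code{theta0 + theta1} at the segment end. The dispersion component uses
#' the closed-form Lorentzian dispersion and the Dawson-function Hilbert
#' pair of the Gaussian (see [pseudoVoigtDispersion()]). Must be applied to
#' a clean (noise-free) segment whose meta still carries its multiplets;
#' labels are unchanged.
#'
#' @param segment a \linkS4class{SpectrumSegment}.
#' @param theta0 zero-order phase, degrees.
#' @param theta1 first-order phase span across the segment, degrees.
#' @return The phase-distorted segment.
#' @export
applyPhaseDistortion <- function(segment, theta0, theta1) {
  stopifnot(is(segment, "SpectrumSegment"))
  if (isTRUE(segment@meta$noiseAdded))
    stop("phase distortion must be applied before noise")
  specs <- segment@meta$multiplets
  if (is.null(specs))
    stop("segment meta carries no multiplet specifications")
  if (theta0 == 0 && theta1 == 0) return(segment)
  n <- length(segment@axis)
  phi <- (theta0 + theta1 * (seq_len(n) - 1) / (n - 1)) * pi / 180
  f <- segment@meta$labelExtentFactor %||% 2
  y <- numeric(n)
  for (sp in specs) {
    ab <- renderMultiplet(sp, segment@axis, f, mode = "absorption")$intensity
    di <- renderMultiplet(sp, segment@axis, f, mode = "dispersion")$intensity
    y <- y + cos(phi) * ab + sin(phi) * di
  }
  segment@intensity <- y
  segment@meta$theta0 <- theta0
  segment@meta$theta1 <- theta1
  segment
}

#' Add a polynomial baseline distortion
#'
#' Adds a polynomial of degree at most \code{degree} evaluated on the
#' normalized coordinate u in [-1, 1]. With explicit \code{coefficients}
#' (ascending powers of u) the polynomial is added as given; otherwise
#' random coefficients are drawn and the curve is rescaled so its maximum
#' absolute deviation is a uniform fraction of \code{maxFrac} times the
#' tallest peak height. Labels are unchanged.
#'
#' @param segment a \linkS4class{SpectrumSegment}.
#' @param coefficients optional explicit polynomial coefficients.
#' @param maxFrac cap on the deviation as a fraction of the tallest peak
#'   (default 0.02).
#' @param degree polynomial degree for random draws (default 3).
#' @return The segment with the baseline added and the coefficients
#'   recorded.
#' @export
applyBaselineDistortion <- function(segment, coefficients = NULL,
                                    maxFrac = 0.02, degree = 3L) {
  stopifnot(is(segment, "SpectrumSegment"))
  n <- length(segment@axis)
  u <- seq(-1, 1, length.out = n)
  if (is.null(coefficients)) {
    if (maxFrac <= 0) return(segment)
    co <- stats::rnorm(degree + 1L)
    curve <- drop(outer(u, 0:degree, `^`) %*% co)
    peak <- max(abs(segment@intensity))
    m <- max(abs(curve))
    amp <- stats::runif(1, 0, maxFrac) * peak
    if (m > 0) {
      co <- co * amp / m
      curve <- curve * amp / m
    }
  } else {
    co <- coefficients
    curve <- drop(outer(u, seq_along(co) - 1, `^`) %*% co)
  }
  segment@intensity <- segment@intensity + curve
  segment@meta$baselineCoef <- co
  segment
}

# truncated geometric draw on 1..maxN with P(n) proportional to r^n
drawRegionCount <- function(r, maxN) {
  p <- r^(seq_len(maxN))
  sample.int(maxN, 1L, prob = p / sum(p))
}

# Draw lineshape/coupling parameters for a given class so that the label
# interval fits inside the usable axis width. The extent cap is honored by
# conditional sampling (gamma from its feasible sub-range, then the J/FWHM
# ratio from the sub-range the drawn gamma allows) rather than by a
# rejection fallback, which would pile wide classes up at the minimum
# width and distort the per-class extent distributions.
drawMultipletParams <- function(classId, cfg, usableHz) {
  f <- cfg@labelExtentFactor
  m <- 2 * (classId - 1)               # extent = m * ratio * gamma + 4f gamma
  gammaMax <- min(cfg@gammaRange[2],
                  usableHz / (4 * f + m * cfg@ratioRange[1]))
  gammaMax <- max(gammaMax, cfg@gammaRange[1])
  gamma <- stats::runif(1, cfg@gammaRange[1], gammaMax)
  ratioMax <- if (m > 0)
    min(cfg@ratioRange[2], (usableHz / gamma - 4 * f) / m)
  else cfg@ratioRange[2]
  ratioMax <- max(ratioMax, cfg@ratioRange[1])
  ratio <- stats::runif(1, cfg@ratioRange[1], ratioMax)
  ls <- stats::runif(1, cfg@lsRange[1], cfg@lsRange[2])
  J <- ratio * 2 * gamma
  list(gamma = gamma, ls = ls, J = J,
       extent = (classId - 1) * J + 2 * f * 2 * gamma)
}

# All centers (on a half-grid-step lattice) whose label interval fits the
# axis and stays >= 1 baseline point away from every existing interval.
feasibleCenters <- function(halfWidthHz, dx, N, intervals) {
  cmin <- halfWidthHz
  cmax <- (N - 1) * dx - halfWidthHz
  if (cmax <= cmin) return(numeric())
  centers <- seq(cmin, cmax, by = dx / 2)
  lo <- centers - halfWidthHz
  hi <- centers + halfWidthHz
  start <- pmax(1L, as.integer(ceiling(lo / dx)) + 1L)
  end <- pmin(N, as.integer(floor(hi / dx)) + 1L)
  ok <- rep(TRUE, length(centers))
  for (j in seq_len(nrow(intervals)))
    ok <- ok & (start > intervals$end[j] + 1L | end < intervals$start[j] - 1L)
  centers[ok]
}

#' Generate one labeled synthetic spectrum segment
#'
#' Draws the number of signal regions from a truncated geometric law,
#' samples one multiplet per region (class uniform over 1..7; line width,
#' Gaussian fraction, J/FWHM ratio, log-uniform amplitude, rooftop tilt
#' within the configured ranges), places the multiplets by rejection
#' sampling so label intervals stay disjoint with at least one baseline
#' point between them, renders the spectrum, and applies phase distortion,
#' baseline distortion, and Gaussian noise in that order. Each point is
#' labeled with its region's class; baseline points carry label 0.
#'
#' Placement rejection keeps the multiplet class fixed and redraws only the
#' geometric parameters, so the class distribution stays uniform. If a
#' region cannot be placed at all the region count is decremented.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed optional seed for this segment; defaults to the config seed.
#' @return A \linkS4class{SpectrumSegment}.
#' @examples
#' seg <- generateSegment(simulationConfig(), seed = 7)
#' table(pointLabels(seg))
#' @export
generateSegment <- function(config, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  seed <- if (is.null(seed)) config@seed else as.integer(seed)
  set.seed(seed)
  cfg <- config
  N <- cfg@nPoints
  sweepHz <- cfg@sweepPpm * cfg@baseFrequencyMHz
  dx <- sweepHz / N
  axis <- (seq_len(N) - 1) * dx
  f <- cfg@labelExtentFactor

  nReg <- drawRegionCount(cfg@regionDecay, cfg@maxRegions)
  specs <- list()
  intervals <- data.frame(class = integer(), start = integer(),
                          end = integer())
  for (reg in seq_len(nReg)) {
    classId <- sample.int(7L, 1L)
    for (paramTry in 1:10) {
      par <- if (paramTry < 10L)
        drawMultipletParams(classId, cfg, 0.9 * sweepHz)
      else {   # last resort: the narrowest admissible shape for this class
        g <- cfg@gammaRange[1]
        J <- cfg@ratioRange[1] * 2 * g
        list(gamma = g, J = J,
             ls = stats::runif(1, cfg@lsRange[1], cfg@lsRange[2]),
             extent = (classId - 1) * J + 2 * f * 2 * g)
      }
      cand <- feasibleCenters(par$extent / 2, dx, N, intervals)
      if (length(cand)) {
        center <- cand[sample.int(length(cand), 1L)]
        lo <- center - par$extent / 2
        hi <- center + par$extent / 2
        start <- max(1L, as.integer(ceiling(lo / dx)) + 1L)
        end <- min(N, as.integer(floor(hi / dx)) + 1L)
        amp <- 10^stats::runif(1, log10(cfg@amplitudeRange[1]),
                               log10(cfg@amplitudeRange[2]))
        tilt <- stats::runif(1, -cfg@rooftopMax, cfg@rooftopMax)
        specs[[length(specs) + 1L]] <-
          multipletSpec(classId, center, par$J, par$gamma, par$ls, amp, tilt)
        intervals <- rbind(intervals,
                           data.frame(class = classId, start = start,
                                      end = end))
        break
      }
      # no feasible position for this width: redraw narrower parameters
      # (class kept fixed); after the retries the region count decrements
    }
  }

  y <- numeric(N)
  labels <- integer(N)
  for (i in seq_along(specs)) {
    r <- renderMultiplet(specs[[i]], axis, f)
    y <- y + r$intensity
    labels[intervals$start[i]:intervals$end[i]] <- intervals$class[i]
  }

  seg <- new("SpectrumSegment", axis = axis, intensity = y,
             labels = labels, sweepWidth = sweepHz,
             baseFrequency = cfg@baseFrequencyMHz,
             meta = list(multiplets = specs, labelIntervals = intervals,
                         labelExtentFactor = f, seed = seed,
                         noiseAdded = FALSE))

  if (length(specs)) {
    if (cfg@phaseMaxDeg > 0) {
      th0 <- stats::runif(1, -cfg@phaseMaxDeg, cfg@phaseMaxDeg)
      th1 <- stats::runif(1, -cfg@phaseMaxDeg, cfg@phaseMaxDeg)
      seg <- applyPhaseDistortion(seg, th0, th1)
    }
    if (cfg@baselineMaxFrac > 0)
      seg <- applyBaselineDistortion(seg, maxFrac = cfg@baselineMaxFrac,
                                     degree = cfg@baselineDegree)
    snr <- 10^stats::runif(1, log10(cfg@snrRange[1]), log10(cfg@snrRange[2]))
    seg <- addNoise(seg, snr)
  }
  seg
}
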