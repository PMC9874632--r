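# Dataset assembly: many segments, deterministic per-segment seeds, splits.

#' Generate a labeled dataset of synthetic segments
#'
#' Per-segment seeds are derived deterministically from the master seed, so
#' the dataset is a pure function of (config, seed): the same call yields
#' bitwise-identical intensities. Split tags are assigned by rounding the
#' cumulative fractions, so e.g. 4 segments at (0.75, 0.25) give 3 train
#' and 1 validation segment.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param nSegments number of segments to generate.
#' @param splitFractions named fractions summing to 1
#'   (default \code{c(train = 0.75, validation = 0.25)}).
#' @param seed master seed (default: config seed).
#' @return A \linkS4class{LabeledDataset}.
#' @examples
#' ds <- generateDataset(simulationConfig(nPoints = 256L, sweepPpm = 0.128),
#'                       4, seed = 1)
#' table(datasetSplit(ds))
#' @export
generateDataset <- function(config, nSegments,
                            splitFractions = c(train = 0.75,
                                               validation = 0.25),
                            seed = NULL) {
  stopifnot(is(config, "SimulationConfig"), nSegments >= 1)
  if (abs(sum(splitFractions) - 1) > 1e-8)
    stop("split fractions must sum to 1, got ",
         paste(splitFractions, collapse = ", "))
  if (is.null(names(splitFractions)) || any(names(splitFractions) == ""))
    stop("split fractions must be named")
  seed <- if (is.null(seed)) config@seed else as.integer(seed)
  set.seed(seed)
  segSeeds <- sample.int(.Machine$integer.max - 1L, nSegments)

  counts <- diff(round(cumsum(c(0, splitFractions)) * nSegments))
  split <- rep(names(splitFractions), counts)

  N <- config@nPoints
  X <- matrix(0, nSegments, N)
  Y <- matrix(0L, nSegments, N)
  regions <- vector("list", nSegments)
  for (i in seq_len(nSegments)) {
    seg <- generateSegment(config, seed = segSeeds[i])
    X[i, ] <- seg@intensity
    Y[i, ] <- seg@labels
    regions[[i]] <- seg@meta$labelIntervals
  }
  new("LabeledDataset", intensity = X, labels = Y, split = split,
      regions = regions, config = config, seed = seed,
      segmentSeeds = segSeeds)
}

#' Multiplet-level class composition of a dataset
#'
#' @param dataset a \linkS4class{LabeledDataset}.
#' @return Integer vector of multiplet counts per class 1..7.
#' @export
classComposition <- function(dataset) {
  stopifnot(is(dataset, "LabeledDataset"))
  cls <- unlist(lapply(dataset@regions, function(r) r$class))
  tabulate(cls, nbins = 7L)
}
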