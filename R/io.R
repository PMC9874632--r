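# I/O: spectrum tables, dataset containers, classifier model files.

DATASET_SCHEMA <- "nmrmultiplet.dataset"
DATASET_VERSION <- 1L
MODEL_SCHEMA <- "nmrmultiplet.model"
MODEL_VERSION <- 1L

# polynomial rolling hash over the serialized object; ties weights to config
contentHash <- function(object) {
  raw <- serialize(object, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a two-column spectrum table
#'
#' Parses a whitespace- or tab-separated table with a header declaring the
#' position unit (\code{position_ppm} or \code{position_hz}) and an
#' \code{intensity} column. Comment lines starting with \code{#} are
#' skipped; a comment of the form \code{# frequency_mhz: 400} (or the
#' \code{frequencyMHz} argument) supplies the spectrometer frequency needed
#' to convert ppm to Hz. A descending axis is accepted and reordered
#' ascending with a recorded flip flag.
#'
#' @param path file path.
#' @param frequencyMHz spectrometer frequency, MHz; required for ppm input
#'   unless declared in the file.
#' @return data.frame(position_hz, intensity) with attributes
#'   \code{units}, \code{frequencyMHz}, \code{flipped}.
#' @export
readSpectrumTable <- function(path, frequencyMHz = NULL) {
  lines <- readLines(path)
  isComment <- grepl("^\\s*#", lines)
  fdecl <- grep("frequency_mhz\\s*:", lines[isComment], value = TRUE)
  if (length(fdecl) && is.null(frequencyMHz))
    frequencyMHz <- as.numeric(sub(".*frequency_mhz\\s*:\\s*", "", fdecl[1]))
  keep <- which(!isComment & nzchar(trimws(lines)))
  if (length(keep) < 3L)
    stop("spectrum table needs a header and at least 2 data rows")
  header <- strsplit(trimws(lines[keep[1]]), "\\s+")[[1]]
  posCol <- grep("^position_(ppm|hz)$", header)
  intCol <- match("intensity", header)
  if (!length(posCol) || is.na(intCol))
    stop("header must declare 'position_ppm' or 'position_hz' and 'intensity'")
  unit <- sub("^position_", "", header[posCol[1]])
  rows <- keep[-1]
  vals <- lapply(rows, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(fields))
    if (anyNA(v) || length(v) < length(header))
      stop(sprintf("non-numeric or incomplete row at line %d: '%s'",
                   i, lines[i]))
    v
  })
  m <- do.call(rbind, vals)
  pos <- m[, posCol[1]]
  int <- m[, intCol]
  if (unit == "ppm") {
    if (is.null(frequencyMHz))
      stop("ppm positions need a spectrometer frequency; add a ",
           "'# frequency_mhz: <value>' line or pass frequencyMHz")
    pos <- pos * frequencyMHz
  }
  d <- diff(pos)
  flipped <- FALSE
  if (all(d < 0)) {
    pos <- rev(pos); int <- rev(int); d <- -rev(d); flipped <- TRUE
  }
  if (any(d <= 0)) {
    bad <- rows[which(d <= 0)[1] + 1L]
    stop("position axis is not strictly monotone at line ", bad)
  }
  out <- data.frame(position_hz = pos, intensity = int)
  attr(out, "units") <- unit
  attr(out, "frequencyMHz") <- frequencyMHz
  attr(out, "flipped") <- flipped
  out
}

#' Write / read a labeled dataset container
#'
#' A single-file container holding the intensity and label matrices, the
#' region tables, split tags, configuration snapshot and all seeds. The
#' write-read round trip is lossless; a container written by a newer schema
#' version is refused rather than reinterpreted.
#'
#' @param dataset a \linkS4class{LabeledDataset}.
#' @param path file path.
#' @return \code{writeDataset} returns \code{path} invisibly;
#'   \code{readDataset} returns the \linkS4class{LabeledDataset}.
#' @export
writeDataset <- function(dataset, path) {
  stopifnot(is(dataset, "LabeledDataset"))
  payload <- list(schema = DATASET_SCHEMA, version = DATASET_VERSION,
                  intensity = dataset@intensity, labels = dataset@labels,
                  split = dataset@split, regions = dataset@regions,
                  config = configAsList(dataset@config),
                  seed = dataset@seed, segmentSeeds = dataset@segmentSeeds)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname writeDataset
#' @export
readDataset <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$schema, DATASET_SCHEMA))
    stop("'", path, "' is not a dataset container")
  if (payload$version > DATASET_VERSION)
    stop("container schema version ", payload$version,
         " is newer than the supported version ", DATASET_VERSION)
  new("LabeledDataset", intensity = payload$intensity,
      labels = payload$labels, split = payload$split,
      regions = payload$regions, config = listAsConfig(payload$config),
      seed = payload$seed, segmentSeeds = payload$segmentSeeds)
}

configAsList <- function(cfg) {
  nm <- slotNames(cfg)
  stats::setNames(lapply(nm, function(s) slot(cfg, s)), nm)
}

listAsConfig <- function(lst) do.call(new, c(list("SimulationConfig"), lst))

netConfigAsList <- function(cfg) {
  nm <- slotNames(cfg)
  stats::setNames(lapply(nm, function(s) slot(cfg, s)), nm)
}

#' Write / read a classifier model file
#'
#' A single archive with the architecture, weights, normalization tag and
#' training history. The architecture is hashed at write time; a file whose
#' weights do not match its configuration hash (or whose weight shapes do
#' not match the architecture) is refused at load time.
#'
#' @param model a \linkS4class{MultipletClassifier}.
#' @param path file path.
#' @return \code{writeClassifier} returns \code{path} invisibly;
#'   \code{readClassifier} the \linkS4class{MultipletClassifier}.
#' @export
writeClassifier <- function(model, path) {
  stopifnot(is(model, "MultipletClassifier"))
  cfgList <- netConfigAsList(model@config)
  payload <- list(schema = MODEL_SCHEMA, version = MODEL_VERSION,
                  config = cfgList, configHash = contentHash(cfgList),
                  weights = model@weights,
                  normalization = model@normalization,
                  history = model@history, trained = model@trained,
                  pointsPerHz = model@pointsPerHz)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$schema, MODEL_SCHEMA))
    stop("'", path, "' is not a classifier model file")
  if (payload$version > MODEL_VERSION)
    stop("model schema version ", payload$version,
         " is newer than the supported version ", MODEL_VERSION)
  if (!identical(contentHash(payload$config), payload$configHash))
    stop("model file refused: configuration hash mismatch")
  config <- do.call(new, c(list("NetworkConfig"), payload$config))
  dims <- nnWeightDims(config)
  w <- payload$weights
  if (!identical(names(w), names(dims)) ||
      !all(vapply(names(dims), function(nm)
        all(dim(w[[nm]]) == dims[[nm]]), logical(1))))
    stop("model file refused: weight shapes do not match the architecture")
  new("MultipletClassifier", config = config, weights = w,
      normalization = payload$normalization, history = payload$history,
      trained = payload$trained, pointsPerHz = payload$pointsPerHz)
}

#' Write predicted labels as a TSV table
#'
#' Columns: point index, position (Hz), predicted label, and one softmax
#' probability column per class.
#'
#' @param prediction a \linkS4class{PredictionResult}.
#' @param axis frequency axis, Hz.
#' @param path output path.
#' @export
writeLabels <- function(prediction, axis, path) {
  probs <- prediction@probabilities
  df <- data.frame(index = seq_along(axis), position_hz = axis,
                   label = prediction@labels)
  pcols <- as.data.frame(probs)
  names(pcols) <- paste0("prob_", seq_len(ncol(probs)) - 1L)
  utils::write.table(cbind(df, pcols), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
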