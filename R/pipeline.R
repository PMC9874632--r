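# End-to-end pipeline: simulate -> train -> predict -> evaluate, with a
# manifest that makes every artifact reproducible from the master seed.

#' Aggregate evaluation of a classifier over a test dataset
#'
#' Predicts every segment, pools the point-wise confusion matrix, extracts
#' prediction regions per segment (tagged with their segment index so
#' matching stays within segments while confidence ranking is global), and
#' computes per-class AP and mAP at each IOU threshold.
#'
#' @param model a trained \linkS4class{MultipletClassifier}.
#' @param dataset a \linkS4class{LabeledDataset} used as test set.
#' @param iouThresholds IOU thresholds for the object-wise metrics.
#' @param majorityWindow optional odd window for [majorityFilter()]
#'   post-processing.
#' @return list(confusion, normalized, metrics, objectwise) where
#'   objectwise maps each threshold to list(perClass, mAP, curve).
#' @export
evaluateClassifier <- function(model, dataset, iouThresholds = c(0.5, 0.75),
                               majorityWindow = NULL) {
  stopifnot(is(model, "MultipletClassifier"), is(dataset, "LabeledDataset"))
  n <- nSegments(dataset)
  K <- model@config@nClasses
  cm <- matrix(0L, K, K, dimnames = list(truth = 0:(K - 1L),
                                         predicted = 0:(K - 1L)))
  predRegions <- vector("list", n)
  truthRegions <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- predict(model, dataset@intensity[i, ])
    labs <- pr@labels
    if (!is.null(majorityWindow)) {
      labs <- majorityFilter(labs, majorityWindow)
      pr@labels <- labs
    }
    cm <- cm + pointwiseConfusion(as.integer(dataset@labels[i, ]), labs, K)
    reg <- extractRegions(pr)
    if (nrow(reg)) reg$segment <- i
    predRegions[[i]] <- reg
    tr <- dataset@regions[[i]]
    if (nrow(tr)) tr$segment <- i
    truthRegions[[i]] <- tr
  }
  pred <- do.call(rbind, predRegions)
  truth <- do.call(rbind, truthRegions)
  objectwise <- lapply(iouThresholds, function(t) {
    m <- meanAveragePrecision(pred, truth, iou = t)
    list(iou = t, perClass = m$perClass, mAP = m$mAP)
  })
  names(objectwise) <- paste0("iou", iouThresholds * 100)
  list(confusion = cm, normalized = normalizeConfusion(cm),
       metrics = classMetrics(cm), objectwise = objectwise,
       predRegions = pred, truthRegions = truth)
}

#' Run the full simulate-train-predict-evaluate pipeline
#'
#' Reproduces the reference experiment layout: a training pool split
#' 75/25 into train and validation, an independently generated test set,
#' training for a fixed number of epochs, and both point-wise and
#' object-wise evaluation. The \code{scale} knob shrinks the full protocol
#' (100,000 pool segments, 10,000 test segments, 33 epochs) for desk-scale
#' runs. One master seed drives data generation, weight initialization and
#' shuffling through a documented derivation (three draws from the master
#' stream).
#'
#' @param outDir output directory; created if needed.
#' @param scale fraction of the full protocol (1 = full).
#' @param seed master seed.
#' @param simConfig a \linkS4class{SimulationConfig}.
#' @param netConfig a \linkS4class{NetworkConfig}.
#' @param epochs override the scaled epoch count.
#' @param batchSize,learningRate training hyper-parameters.
#' @param iouThresholds IOU thresholds for evaluation.
#' @param majorityWindow optional majority-filter window.
#' @param verbose log training progress.
#' @return list(manifest, results) invisibly; all reports are written under
#'   \code{outDir}.
#' @export
runPipeline <- function(outDir, scale = 1, seed = 1L,
                        simConfig = simulationConfig(),
                        netConfig = networkConfig(), epochs = NULL,
                        batchSize = 64L, learningRate = 1e-3,
                        iouThresholds = c(0.5, 0.75),
                        majorityWindow = NULL, verbose = FALSE) {
  stopifnot(scale > 0, scale <= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  nPool <- max(8L, as.integer(round(100000 * scale)))
  nTest <- max(4L, as.integer(round(10000 * scale)))
  if (is.null(epochs)) epochs <- max(1L, as.integer(round(33 * scale)))

  set.seed(seed)
  derived <- sample.int(2147483646L, 3L)  # pool data, test data, training

  pool <- generateDataset(simConfig, nPool,
                          c(train = 0.75, validation = 0.25),
                          seed = derived[1])
  test <- generateDataset(simConfig, nTest, c(test = 1), seed = derived[2])

  model <- buildNetwork(netConfig, seed = derived[3])
  tc <- trainingConfig(epochs = epochs, batchSize = batchSize,
                       learningRate = learningRate, seed = derived[3])
  model <- trainClassifier(model, pool, tc, verbose = verbose)

  results <- evaluateClassifier(model, test, iouThresholds, majorityWindow)

  modelPath <- file.path(outDir, "model.rds")
  writeClassifier(model, modelPath)
  histPath <- file.path(outDir, "history.csv")
  utils::write.csv(model@history, histPath, row.names = FALSE)
  cmPath <- file.path(outDir, "confusion.csv")
  utils::write.csv(results$confusion, cmPath)
  metricsPath <- file.path(outDir, "metrics.json")
  ow <- lapply(results$objectwise, function(o)
    list(iou = o$iou, perClass = as.list(o$perClass), mAP = o$mAP))
  jsonlite::write_json(list(pointwise = results$metrics, objectwise = ow),
                       metricsPath, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)

  outputs <- c(model = modelPath, history = histPath, confusion = cmPath,
               metrics = metricsPath)
  manifest <- list(
    command = "pipeline",
    version = as.character(utils::packageVersion("nmrmultiplet")),
    seed = seed, derivedSeeds = derived, scale = scale,
    layout = list(pool = nPool, train = sum(pool@split == "train"),
                  validation = sum(pool@split == "validation"),
                  test = nTest, epochs = epochs),
    simConfig = configAsList(simConfig),
    netConfig = netConfigAsList(netConfig),
    outputs = as.list(outputs),
    digests = as.list(tools::md5sum(unname(outputs))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results, model = model))
}
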