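# Training: per-point categorical cross-entropy minimized with Adam.

#' Training configuration
#'
#' @param epochs training epochs (default 33).
#' @param batchSize minibatch size (default 64).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param optimizer optimizer name; only "adam" is implemented.
#' @param validationFraction fraction carved from the training split when
#'   the dataset has no validation tag (default 0.25).
#' @param seed seed controlling minibatch shuffling.
#' @param clipNorm global gradient-norm clip; 0 disables clipping.
#' @param lrDecay per-epoch multiplicative learning-rate decay (1 = none).
#' @param classWeights optional per-class loss weights (length
#'   \code{nClasses}); off by default.
#' @return A list with class \code{"TrainingConfig"}.
#' @export
trainingConfig <- function(epochs = 33L, batchSize = 64L,
                           learningRate = 1e-3, optimizer = "adam",
                           validationFraction = 0.25, seed = 1L,
                           clipNorm = 1, lrDecay = 1, classWeights = NULL) {
  stopifnot(epochs >= 1, batchSize >= 1, learningRate > 0,
            validationFraction > 0, validationFraction < 1, clipNorm >= 0,
            lrDecay > 0, lrDecay <= 1)
  if (!identical(optimizer, "adam"))
    stop("only the 'adam' optimizer is implemented")
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, optimizer = optimizer,
                 validationFraction = validationFraction,
                 seed = as.integer(seed), clipNorm = clipNorm,
                 lrDecay = lrDecay, classWeights = classWeights),
            class = "TrainingConfig")
}

#' Train the point-wise classifier
#'
#' Minimizes the per-point categorical cross-entropy over the training
#' split with Adam, tracking loss and point-wise accuracy on both the
#' training and the validation split each epoch. Inputs are normalized per
#' segment by their maximum absolute intensity (the convention recorded in
#' the classifier). Deterministic given the seeds.
#'
#' @param model an untrained (or previously trained)
#'   \linkS4class{MultipletClassifier} from [buildNetwork()].
#' @param dataset a \linkS4class{LabeledDataset} with train (and ideally
#'   validation) split tags.
#' @param tconfig a [trainingConfig()].
#' @param verbose log per-epoch metrics to stderr.
#' @return The trained classifier with its history filled in.
#' @export
trainClassifier <- function(model, dataset, tconfig = trainingConfig(),
                            verbose = FALSE) {
  stopifnot(is(model, "MultipletClassifier"), is(dataset, "LabeledDataset"),
            inherits(tconfig, "TrainingConfig"))
  K <- model@config@nClasses
  if (any(dataset@labels < 0L | dataset@labels >= K))
    stop("labels must lie in 0..", K - 1L)
  if (ncol(dataset@intensity) < max(model@config@convKernels))
    stop("segments are shorter than the largest convolution kernel")

  itr <- which(dataset@split == "train")
  ival <- which(dataset@split == "validation")
  if (!length(itr)) stop("dataset has no 'train' split")
  if (!length(ival)) {
    nv <- max(1L, round(length(itr) * tconfig$validationFraction))
    ival <- utils::tail(itr, nv)
    itr <- setdiff(itr, ival)
  }

  normRows <- function(M)
    t(apply(M, 1, applyNormalization, tag = model@normalization))
  Xtr <- t(normRows(dataset@intensity[itr, , drop = FALSE]))
  Ytr <- t(dataset@labels[itr, , drop = FALSE])
  Xval <- t(normRows(dataset@intensity[ival, , drop = FALSE]))
  Yval <- t(dataset@labels[ival, , drop = FALSE])

  cw <- tconfig$classWeights
  if (!is.null(cw) && length(cw) != K)
    stop("classWeights must have length ", K)
  fit <- cpp_nn_train(model@weights, cfgToCpp(model@config), Xtr, Ytr,
                      Xval, Yval,
                      list(epochs = tconfig$epochs,
                           batch = tconfig$batchSize,
                           lr = tconfig$learningRate, seed = tconfig$seed,
                           clip_norm = tconfig$clipNorm,
                           lr_decay = tconfig$lrDecay,
                           class_weights = cw, verbose = verbose))
  model@weights <- fit$weights
  model@history <- as.data.frame(fit$history)
  model@trained <- TRUE
  model
}
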