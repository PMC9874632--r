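# Network construction: weight template, initialization, parameter count.
# The canonical weight order must match the C++ engine:
# convW_i..., convb_i..., d0W, d0b, fWx, fWh, fb, bWx, bWh, bb, sW_j, sb_j.

nnWeightDims <- function(config) {
  ks <- config@convKernels
  Fn <- config@convFilters
  C0 <- length(ks) * Fn
  D <- config@postConvDenseUnits
  U <- config@lstmUnits
  st <- config@denseStack
  dims <- list()
  for (i in seq_along(ks)) dims[[sprintf("conv_W%d", i)]] <- c(Fn, ks[i])
  for (i in seq_along(ks)) dims[[sprintf("conv_b%d", i)]] <- c(Fn, 1L)
  dims$d0_W <- c(D, C0); dims$d0_b <- c(D, 1L)
  dims$lstm_f_Wx <- c(4L * U, D); dims$lstm_f_Wh <- c(4L * U, U)
  dims$lstm_f_b <- c(4L * U, 1L)
  dims$lstm_b_Wx <- c(4L * U, D); dims$lstm_b_Wh <- c(4L * U, U)
  dims$lstm_b_b <- c(4L * U, 1L)
  inSize <- 2L * U
  for (j in seq_along(st)) {
    dims[[sprintf("stack_W%d", j)]] <- c(st[j], inSize)
    dims[[sprintf("stack_b%d", j)]] <- c(st[j], 1L)
    inSize <- st[j]
  }
  dims
}

# canonical list passed to the C++ engine
cfgToCpp <- function(config) {
  list(kernels = config@convKernels, filters = config@convFilters,
       d0 = config@postConvDenseUnits, lstm = config@lstmUnits,
       stack = config@denseStack)
}

#' Number of trainable parameters
#'
#' For a \linkS4class{NetworkConfig} the count is computed in closed form
#' from the layer sizes; for a \linkS4class{MultipletClassifier} it is the
#' total number of scalars in the weight list. The two always agree. The
#' default configuration has 1,225,606 trainable parameters.
#'
#' @param object a network configuration or classifier.
#' @return Integer parameter count.
#' @examples
#' countParameters(networkConfig())
#' @export
setGeneric("countParameters", function(object)
  standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "NetworkConfig", function(object) {
  sum(vapply(nnWeightDims(object), prod, numeric(1)))
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "MultipletClassifier", function(object) {
  sum(vapply(object@weights, length, numeric(1)))
})

#' Build an untrained point-wise classifier
#'
#' Initializes all weight matrices (Glorot-uniform kernels, zero biases,
#' LSTM forget-gate bias 1) for the given architecture. The network is
#' length-agnostic: any input of at least the largest kernel length maps to
#' an equally long sequence of softmax rows.
#'
#' @param config a \linkS4class{NetworkConfig}.
#' @param seed seed for the weight initialization.
#' @param normalization input-normalization convention: "zscore" (per-segment
#'   standardization; default — it trains markedly faster) or "maxabs"
#'   (division by the maximum absolute intensity). The tag is stored with
#'   the model so training and prediction always agree.
#' @return An untrained \linkS4class{MultipletClassifier}.
#' @examples
#' net <- buildNetwork(networkConfig(convKernels = c(4L, 8L),
#'                     convFilters = 4L, postConvDenseUnits = 8L,
#'                     lstmUnits = 8L, denseStack = c(16L, 8L)))
#' @export
buildNetwork <- function(config, seed = 1L,
                         normalization = c("zscore", "maxabs")) {
  stopifnot(is(config, "NetworkConfig"))
  normalization <- match.arg(normalization)
  validObject(config)
  set.seed(seed)
  dims <- nnWeightDims(config)
  U <- config@lstmUnits
  orth <- function(n) qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  weights <- lapply(names(dims), function(nm) {
    d <- dims[[nm]]
    if (grepl("_b[0-9]*$", nm)) {
      b <- matrix(0, d[1], d[2])
      if (grepl("^lstm", nm)) b[(U + 1):(2 * U), 1] <- 1  # forget gate
      b
    } else if (grepl("_Wh$", nm)) {
      # orthogonal recurrent kernel, one block per gate
      do.call(rbind, lapply(1:4, function(i) orth(U)))
    } else {
      lim <- sqrt(6 / (d[1] + d[2]))
      matrix(stats::runif(prod(d), -lim, lim), d[1], d[2])
    }
  })
  names(weights) <- names(dims)
  new("MultipletClassifier", config = config, weights = weights,
      normalization = normalization, history = data.frame(),
      trained = FALSE, pointsPerHz = 5)
}

# normalize one segment according to a classifier's stored convention
applyNormalization <- function(x, tag) {
  switch(tag,
         maxabs = normalizeSegment(x),
         zscore = {
           s <- stats::sd(x)
           if (s == 0) x - mean(x) else (x - mean(x)) / s
         },
         stop("unknown normalization convention '", tag, "'"))
}

#' Normalize a spectrum segment for the network
#'
#' Divides by the maximum absolute intensity so the tallest feature has
#' height 1; an all-zero input passes through unchanged. Idempotent. The
#' convention tag is stored in the classifier so training and prediction
#' agree.
#'
#' @param x numeric intensity vector.
#' @return Normalized vector.
#' @examples
#' normalizeSegment(c(0, 5, 10))   # c(0, 0.5, 1)
#' @export
normalizeSegment <- function(x) {
  m <- max(abs(x))
  if (m == 0) x else x / m
}
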