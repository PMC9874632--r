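# small architecture used throughout the cheap network tests
tinyNet <- function(seed = 2) {
  buildNetwork(networkConfig(convKernels = c(3L, 7L), convFilters = 4L,
                             postConvDenseUnits = 8L, lstmUnits = 6L,
                             denseStack = c(12L, 8L)), seed = seed)
}

test_that("the default architecture reproduces its published parameter count", {
  cfg <- networkConfig()
  expect_identical(as.integer(countParameters(cfg)), 1225606L)
  # the count is a pure function of the configuration
  expect_identical(countParameters(networkConfig()), countParameters(cfg))
})

test_that("parameter counting agrees between the closed form and the weights", {
  net <- tinyNet()
  expect_equal(countParameters(net), countParameters(net@config))
  # component counts: conv branch k=4 with 1->16 channels costs 80; a
  # 64->8 dense layer with bias costs 520
  dims <- nmrmultiplet:::nnWeightDims(
    networkConfig(convKernels = 4L, convFilters = 16L,
                  postConvDenseUnits = 4L, lstmUnits = 32L,
                  denseStack = c(8L), nClasses = 8L))
  expect_equal(prod(dims$conv_W1) + prod(dims$conv_b1), 80)
  expect_equal(prod(dims$stack_W1) + prod(dims$stack_b1), 520)  # 2U=64 -> 8
})

test_that("invalid architectures are rejected", {
  expect_error(networkConfig(denseStack = c(128L, 256L, 8L)), "decreasing")
  expect_error(networkConfig(denseStack = c(128L, 16L), nClasses = 8L),
               "nClasses")
})

test_that("the network is length-agnostic and outputs softmax rows", {
  net <- tinyNet()
  for (n in c(32L, 57L, 128L)) {
    p <- predict(net, rnorm(n))
    expect_equal(dim(probabilities(p)), c(n, 8L))
    expect_true(all(abs(rowSums(probabilities(p)) - 1) < 1e-5))
    expect_true(all(pointLabels(p) %in% 0:7))
  }
})

test_that("inputs shorter than the largest kernel are rejected at predict time", {
  net <- tinyNet()
  expect_error(predict(net, rnorm(5)), "largest kernel")
})

test_that("prediction is deterministic and ties break toward the lowest class", {
  net <- tinyNet()
  x <- rnorm(64)
  expect_identical(probabilities(predict(net, x)),
                   probabilities(predict(net, x)))
  probs <- matrix(c(0.2, 0.1, 0.25, 0.1, 0.05, 0.25, 0.03, 0.02), 1, 8)
  expect_identical(nmrmultiplet:::argmaxLabels(probs), 2L)
  expect_identical(nmrmultiplet:::argmaxLabels(matrix(0.125, 1, 8)), 0L)
})

test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(42)
  cfg <- networkConfig(convKernels = c(3L, 5L), convFilters = 2L,
                       postConvDenseUnits = 4L, lstmUnits = 3L,
                       denseStack = c(6L, 4L), nClasses = 4L)
  net <- buildNetwork(cfg, seed = 2)
  N <- 12L; B <- 2L
  X <- matrix(rnorm(N * B), N, B)
  Y <- matrix(sample(0:3, N * B, TRUE), N, B)
  cc <- nmrmultiplet:::cfgToCpp(cfg)
  lg <- nmrmultiplet:::cpp_nn_loss_grad(net@weights, cc, X, Y, NULL)
  eps <- 1e-6
  for (nm in names(net@weights)) {
    W <- net@weights[[nm]]
    g <- lg$grads[[nm]]
    for (i in sample(length(W), min(4, length(W)))) {
      wp <- net@weights; wp[[nm]][i] <- W[i] + eps
      wm <- net@weights; wm[[nm]][i] <- W[i] - eps
      num <- (nmrmultiplet:::cpp_nn_loss_grad(wp, cc, X, Y, NULL)$loss -
                nmrmultiplet:::cpp_nn_loss_grad(wm, cc, X, Y, NULL)$loss) /
        (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("segment normalization is max-abs, zero-safe and idempotent", {
  expect_equal(normalizeSegment(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(normalizeSegment(numeric(4)), numeric(4))
  x <- rnorm(50) * 37
  expect_equal(normalizeSegment(normalizeSegment(x)), normalizeSegment(x))
})

test_that("resampling hits the target density and preserves constants", {
  ax <- seq(0, 100, by = 0.2)        # 5 points per Hz
  y <- sin(ax / 3)
  same <- resampleSpectrum(ax, y, 5)
  expect_equal(same$axis, ax)
  expect_equal(same$intensity, y, tolerance = 1e-12)
  dbl <- resampleSpectrum(ax, y, 10)
  expect_equal(length(dbl$axis), 2L * length(ax) - 1L)
  expect_equal(diff(dbl$axis[1:2]), 0.1)
  const <- resampleSpectrum(ax, rep(3.3, length(ax)), 7)
  expect_true(all(const$intensity == 3.3))
  # back-map carries original points to their nearest resampled index
  expect_equal(dbl$backMap, seq(1L, by = 2L, length.out = length(ax)))
  expect_error(resampleSpectrum(c(1, 2, 2, 3), 1:4, 5), "monotone")
})

test_that("the majority filter takes windowed modes and keeps originals on ties", {
  expect_identical(majorityFilter(c(3L, 1L, 2L), 1L), c(3L, 1L, 2L))
  expect_identical(majorityFilter(c(1L, 1L, 2L, 1L, 1L), 5L), rep(1L, 5))
  expect_identical(majorityFilter(rep(4L, 9), 5L), rep(4L, 9))
  expect_error(majorityFilter(c(1L, 2L), 4L), "odd")
  # never introduces a label absent from the window
  set.seed(8)
  for (i in 1:25) {
    lab <- sample(0:3, 40, TRUE)
    out <- majorityFilter(lab, 7L)
    h <- 3L
    for (k in seq_along(out)) {
      win <- lab[max(1, k - h):min(40, k + h)]
      expect_true(out[k] %in% win)
    }
  }
})
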