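# One shared scaled-down training run, reused by every test that needs a
# trained classifier (learning sanity, AP monotonicity, translation
# robustness). Memoized so the suite trains exactly once per session.
#
# Protocol: 2,000 easy-mode segments of 512 points (SNR >= 10^1.5,
# J/FWHM >= 4, no phase/baseline distortion) as the training set, 400
# independently generated segments held out, a reduced network of the same
# architecture family, 10 epochs.

sanityNetworkConfig <- function() {
  networkConfig(convKernels = c(4L, 16L, 64L, 256L), convFilters = 16L,
                postConvDenseUnits = 64L, lstmUnits = 48L,
                denseStack = c(128L, 64L, 32L, 8L))
}

sanityFit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- easySimulationConfig(nPoints = 512L)
    pool <- generateDataset(cfg, 2400,
                            c(train = 5 / 6, validation = 1 / 6),
                            seed = 20260921L)
    model <- buildNetwork(sanityNetworkConfig(), seed = 301L)
    model <- trainClassifier(model, pool,
                             trainingConfig(epochs = 10L, batchSize = 8L,
                                            learningRate = 8e-3,
                                            lrDecay = 0.75, clipNorm = 0,
                                            seed = 301L))
    test <- generateDataset(cfg, 300, c(test = 1), seed = 9042L)
    cache <<- list(model = model, pool = pool, test = test, config = cfg)
    cache
  }
})
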