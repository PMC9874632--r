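mkSinglet <- function(nPoints = 2048L, gamma = 0.5, amplitude = 1,
                      center = 20, lsMix = 0) {
  sweep <- nPoints / 5   # keep 5 points per Hz
  ax <- (seq_len(nPoints) - 1) * sweep / nPoints
  sp <- multipletSpec(1, center, 0, gamma, lsMix, amplitude)
  r <- renderMultiplet(sp, ax)
  labels <- integer(nPoints)
  labels[r$start:r$end] <- 1L
  new("SpectrumSegment", axis = ax, intensity = r$intensity,
      labels = labels, sweepWidth = sweep, baseFrequency = 400,
      meta = list(multiplets = list(sp),
                  labelIntervals = data.frame(class = 1L, start = r$start,
                                              end = r$end),
                  labelExtentFactor = 2, noiseAdded = FALSE))
}

test_that("added noise matches the requested SNR on a long baseline stretch", {
  seg <- mkSinglet(amplitude = 100)
  set.seed(99)
  noisy <- addNoise(seg, 10)
  base <- which(noisy@labels == 0L & noisy@axis > 60)
  expect_gt(length(base), 500)
  expect_equal(sd(noisy@intensity[base]), 10, tolerance = 0.05)
  expect_identical(noisy@labels, seg@labels)
})

test_that("noise is deterministic under a fixed seed and absent at infinite SNR", {
  seg <- mkSinglet()
  set.seed(1); a <- addNoise(seg, 20)
  set.seed(1); b <- addNoise(seg, 20)
  expect_identical(a@intensity, b@intensity)
  expect_identical(addNoise(seg, Inf)@intensity, seg@intensity)
  zero <- seg; zero@intensity <- numeric(length(seg@axis))
  expect_error(addNoise(zero, 10), "all-zero")
})

test_that("zero phase distortion is the identity", {
  seg <- mkSinglet()
  out <- applyPhaseDistortion(seg, 0, 0)
  expect_identical(out@intensity, seg@intensity)
})

test_that("a 90-degree phase turns a Lorentzian singlet into its antisymmetric dispersion", {
  seg <- mkSinglet(gamma = 1, center = 204.8, nPoints = 2048L)
  out <- applyPhaseDistortion(seg, 90, 0)
  ctr <- which.min(abs(seg@axis - 204.8))
  expect_lt(abs(out@intensity[ctr]), 1e-6)
  k <- 1:300
  expect_equal(out@intensity[ctr + k], -out@intensity[ctr - k],
               tolerance = 1e-8)
  # closed-form Lorentzian dispersion scaled to the absorption height
  x <- seg@axis[ctr + k] - 204.8
  expect_equal(out@intensity[ctr + k], x * 1 / (x^2 + 1), tolerance = 1e-6)
})

test_that("a small phase error reduces the apex by roughly cos(theta)", {
  seg <- mkSinglet(gamma = 1, center = 100)
  out <- applyPhaseDistortion(seg, 5, 0)
  expect_equal(max(out@intensity) / max(seg@intensity), cos(5 * pi / 180),
               tolerance = 1e-3)
  expect_identical(out@labels, seg@labels)
})

test_that("phase distortion refuses to run after noise", {
  seg <- mkSinglet()
  set.seed(2)
  noisy <- addNoise(seg, 10)
  expect_error(applyPhaseDistortion(noisy, 5, 0), "before noise")
})

test_that("baseline distortion honors explicit coefficients and the amplitude cap", {
  seg <- mkSinglet()
  expect_identical(applyBaselineDistortion(seg, coefficients = 0)@intensity,
                   seg@intensity)
  shifted <- applyBaselineDistortion(seg, coefficients = 3.5)
  expect_equal(shifted@intensity, seg@intensity + 3.5)
  peak <- max(abs(seg@intensity))
  for (s in 1:20) {
    set.seed(s)
    out <- applyBaselineDistortion(seg, maxFrac = 0.02)
    expect_lte(max(abs(out@intensity - seg@intensity)), 0.02 * peak + 1e-12)
  }
})

test_that("default segments use the training grid: 1024 points over 0.512 ppm at 400 MHz", {
  seg <- generateSegment(simulationConfig(), seed = 3)
  expect_length(seg@intensity, 1024)
  expect_equal(seg@sweepWidth, 204.8)
  dx <- diff(seg@axis[1:2])
  expect_equal(1 / dx, 5, tolerance = 1e-6)   # 5 points per Hz
  expect_equal(seg@baseFrequency, 400)
})

test_that("a single-region config yields exactly one maximal nonzero run", {
  cfg <- simulationConfig(maxRegions = 1L)
  for (s in 1:10) {
    seg <- generateSegment(cfg, seed = s)
    iv <- labelIntervals(seg)
    expect_equal(nrow(iv), 1L)
    r <- rle(seg@labels)
    runs <- which(r$values != 0L)
    expect_length(runs, 1L)
    expect_equal(r$values[runs], iv$class)
  }
})

test_that("label runs and multiplet specs are in bijection with baseline gaps", {
  cfg <- simulationConfig()
  for (s in 1:60) {
    seg <- generateSegment(cfg, seed = 1000 + s)
    iv <- labelIntervals(seg)
    expect_equal(length(seg@meta$multiplets), nrow(iv))
    r <- rle(seg@labels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L
    expect_equal(sum(keep), nrow(iv))
    got <- data.frame(class = r$values[keep], start = starts[keep],
                      end = ends[keep])
    ord <- order(iv$start)
    expect_equal(got$class, iv$class[ord])
    expect_equal(got$start, iv$start[ord])
    expect_equal(got$end, iv$end[ord])
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] - got$end[-nrow(got)] >= 2))
    # spec classes match interval classes
    cls <- vapply(seg@meta$multiplets, function(m) m@classId, integer(1))
    expect_equal(cls, iv$class)
  }
})

test_that("datasets are reproducible and split by rounded fractions", {
  cfg <- simulationConfig(nPoints = 256L, sweepPpm = 0.128)
  a <- generateDataset(cfg, 4, c(train = 0.75, validation = 0.25), seed = 5)
  b <- generateDataset(cfg, 4, c(train = 0.75, validation = 0.25), seed = 5)
  expect_identical(a@intensity, b@intensity)
  expect_identical(a@labels, b@labels)
  expect_equal(sum(a@split == "train"), 3L)
  expect_equal(sum(a@split == "validation"), 1L)
  expect_error(generateDataset(cfg, 4, c(train = 0.7, validation = 0.2)),
               "sum to 1")
})
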