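test_that("binomial amplitudes follow Pascal's triangle, max-normalized", {
  expect_equal(binomialAmplitudes(1), 1)
  expect_equal(binomialAmplitudes(3), c(0.5, 1, 0.5))
  expect_equal(binomialAmplitudes(7) * 20, c(1, 6, 15, 20, 15, 6, 1))
  expect_error(binomialAmplitudes(0), "1..7")
  expect_error(binomialAmplitudes(8), "1..7")
})

test_that("rooftop tilt scales amplitudes linearly and rejects sign flips", {
  expect_equal(applyRooftop(c(1, 1), 0), c(1, 1))
  expect_equal(applyRooftop(c(1, 1), 0.2), c(0.8, 1.2))
  expect_equal(applyRooftop(1, 0.2), 1)               # singlet: no tilt axis
  expect_equal(applyRooftop(c(1, 2, 1), 0.1), c(0.9, 2, 1.1))
  expect_error(applyRooftop(c(1, 1), 1.5), "non-positive")
})

test_that("a rendered singlet has its label interval centered on the apex", {
  ax <- (0:1023) * 0.2          # exact 5 points per Hz; 100 Hz on-grid
  sp <- multipletSpec(1, 100, 0, 0.8, lsMix = 0.3, amplitude = 5)
  r <- renderMultiplet(sp, ax)
  apex <- which.max(r$intensity)
  center <- (r$start + r$end) / 2
  expect_lt(abs(apex - center), 1.01)
  expect_equal(max(r$intensity), 5, tolerance = 1e-3)
  # interval is one contiguous run containing the apex
  expect_true(r$start <= apex && apex <= r$end)
})

test_that("a well-resolved triplet shows 1:2:1 local maxima", {
  ax <- seq(0, 204.8, length.out = 4096)
  gamma <- 0.5
  sp <- multipletSpec(3, 100, 10 * 2 * gamma, gamma, amplitude = 1)
  r <- renderMultiplet(sp, ax)
  y <- r$intensity
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  locmax <- locmax[y[locmax] > 0.05]
  expect_length(locmax, 3)
  h <- y[locmax]
  expect_equal(h[2] / h[1], 2, tolerance = 0.01)
  expect_equal(h[2] / h[3], 2, tolerance = 0.01)
})

test_that("zero amplitude renders an all-zero curve and out-of-range peaks are rejected", {
  ax <- seq(0, 100, length.out = 512)
  expect_equal(renderMultiplet(multipletSpec(2, 50, 5, 1, amplitude = 0),
                               ax)$intensity, numeric(512))
  expect_error(renderMultiplet(multipletSpec(7, 95, 30, 2), ax), "outside")
})

test_that("peak centers are symmetric around the multiplet center", {
  sp <- multipletSpec(4, 80, 6, 1)
  pc <- peakCenters(sp)
  expect_equal(pc, c(71, 77, 83, 89))
  expect_equal(mean(pc), 80)
  expect_equal(diff(pc), rep(6, 3))
})
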