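test_that("pseudo-Voigt is unit height at center and half height at one HWHM for every mix", {
  for (ls in seq(0, 1, by = 0.1)) {
    for (gamma in c(0.5, 1, 3.7, 7)) {
      expect_equal(pseudoVoigt(0, gamma, ls), 1)
      expect_equal(pseudoVoigt(gamma, gamma, ls), 0.5, tolerance = 1e-12)
      expect_equal(pseudoVoigt(-gamma, gamma, ls), 0.5, tolerance = 1e-12)
    }
  }
})

test_that("mixing limits reproduce the pure Lorentzian and Gaussian closed forms", {
  x <- seq(-30, 30, by = 0.05)
  gamma <- 1.3
  sigma <- gamma / sqrt(2 * log(2))
  expect_equal(pseudoVoigt(x, gamma, 0), gamma^2 / (x^2 + gamma^2),
               tolerance = 1e-12)
  expect_equal(pseudoVoigt(x, gamma, 1), exp(-x^2 / (2 * sigma^2)),
               tolerance = 1e-12)
  # pure Lorentzian quarter value at x = 2 gamma: 1/5
  expect_equal(pseudoVoigt(2, 1, 0), 0.2)
})

test_that("pseudo-Voigt is symmetric, positive, and bounded by 1", {
  x <- seq(0.01, 50, length.out = 200)
  for (ls in c(0, 0.5, 1)) {
    v <- pseudoVoigt(x, 2, ls)
    expect_equal(v, pseudoVoigt(-x, 2, ls))
    expect_true(all(v > 0 & v <= 1))
  }
})

test_that("invalid lineshape parameters are rejected with a diagnostic", {
  expect_error(pseudoVoigt(0, 0, 0.5), "gamma")
  expect_error(pseudoVoigt(0, -1, 0.5), "gamma")
  expect_error(pseudoVoigt(0, 1, 1.5), "lsMix")
  expect_error(pseudoVoigtDispersion(0, -2, 0.5), "gamma")
})

test_that("Lorentzian dispersion matches its closed form and is antisymmetric", {
  x <- seq(-20, 20, by = 0.1)
  gamma <- 2
  d <- pseudoVoigtDispersion(x, gamma, 0)
  expect_equal(d, x * gamma / (x^2 + gamma^2), tolerance = 1e-12)
  expect_equal(pseudoVoigtDispersion(0, gamma, 0.7), 0)
  expect_equal(d, -rev(d))
})

test_that("the Dawson evaluation matches independent references", {
  skip_if_not_installed("pracma")
  # erfi-based closed form is trustworthy up to |x| ~ 5
  x <- seq(-5, 5, by = 0.037)
  ref <- sqrt(pi) / 2 * exp(-x^2) * pracma::erfi(x)
  expect_lt(max(abs(nmrmultiplet:::dawsonF(x) - ref)), 1e-6)
  # large-argument asymptotic series takes over beyond that
  xl <- seq(5, 40, by = 0.21)
  asym <- 1 / (2 * xl) * (1 + 1 / (2 * xl^2) + 3 / (4 * xl^4) +
                            15 / (8 * xl^6) + 105 / (16 * xl^8))
  expect_lt(max(abs(nmrmultiplet:::dawsonF(xl) - asym)), 1e-6)
})

test_that("Gaussian dispersion agrees with a numerical Hilbert transform", {
  # long grid so FFT edge effects stay away from the window of interest
  n <- 8192
  x <- seq(-400, 400, length.out = n)
  gamma <- 2
  ab <- pseudoVoigt(x, gamma, 1)
  hil <- oracle_fft_hilbert(ab)
  disp <- pseudoVoigtDispersion(x, gamma, 1)
  mid <- which(abs(x) < 50)
  # fix the transform's sign convention on the Lorentzian closed form
  abL <- pseudoVoigt(x, gamma, 0)
  hilL <- oracle_fft_hilbert(abL)
  sgn <- sign(sum(hilL[mid] * (x[mid] * gamma / (x[mid]^2 + gamma^2))))
  expect_lt(max(abs(sgn * hil[mid] - disp[mid])), 2e-3)
})
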