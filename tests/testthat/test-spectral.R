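test_that("symmetrization reflects the signal about the window centre", {
  expect_equal(symmetrize_pcf(c(10, 20, 30), X = 4), c(30, 20, 10, 20))
  expect_equal(symmetrize_pcf(rep(1, 6), X = 10), rep(1, 10))
  set.seed(3)
  f <- runif(9)
  X <- 16
  ft <- symmetrize_pcf(f, X = X)
  for (d in 0:(X / 2 - 1)) expect_equal(ft[X / 2 + d + 1], f[d + 1])
  # evenness about the centre
  for (d in 1:(X / 2 - 1)) expect_equal(ft[X / 2 - d + 1], ft[X / 2 + d + 1])
  expect_error(symmetrize_pcf(1:5, X = 16), "length")
})

test_that("rescaled DFT matches direct summation including c_k", {
  set.seed(17)
  for (X in c(8, 20, 100)) {
    f <- runif(X / 2 + 1, 0.5, 1.5)
    ft <- symmetrize_pcf(f, X = X)
    sp <- pcf_dft(ft)
    expect_equal(sp$coefficients, brute_dft(ft), tolerance = 1e-12)
  }
})

test_that("pure cosines land on single wavenumbers with amplitude 1/2", {
  X <- 40
  grid <- -pi + 2 * pi * (0:(X - 1)) / X
  for (m in c(3, 7, 19)) {
    sp <- pcf_dft(cos(m * grid))
    expect_equal(sp$coefficients[m + 1], 0.5, tolerance = 1e-10)
    expect_lt(max(abs(sp$coefficients[-c(1, m + 1)])), 1e-10)
    expect_equal(sp$coefficients, brute_dft(cos(m * grid)),
                 tolerance = 1e-10)
  }
  # constant signal: only the mean coefficient survives
  sp0 <- pcf_dft(rep(2.5, X))
  expect_equal(sp0$coefficients[1], 2.5)
  expect_lt(max(abs(sp0$coefficients[-1])), 1e-12)
  # k = 0 coefficient is the arithmetic mean of the symmetrized signal
  set.seed(8)
  ft <- symmetrize_pcf(runif(X / 2 + 1), X = X)
  expect_equal(pcf_dft(ft)$coefficients[1], mean(ft))
})

test_that("the full set of modes reconstructs the signal", {
  set.seed(23)
  X <- 24
  f <- runif(X / 2 + 1, 0.8, 1.2)
  sp <- pcf_dft(symmetrize_pcf(f, X = X))
  co <- sp$coefficients
  recon <- vapply(0:(X / 2), function(d) {
    co[1] +
      sum(2 * co[2:(X / 2)] * cos(2 * pi * (1:(X / 2 - 1)) * d / X)) +
      2 * co[X / 2 + 1] * cos(pi * d)
  }, numeric(1))
  expect_equal(recon, f, tolerance = 1e-10)
})

test_that("dominant wavenumbers are interior power peaks, ranked", {
  X <- 60
  grid <- -pi + 2 * pi * (0:(X - 1)) / X
  one <- pcf_dft(1 + 0.2 * cos(17 * grid))
  expect_equal(dominant_wavenumbers(one), 17L)
  two <- pcf_dft(1 + 0.1 * cos(9 * grid) + 0.3 * cos(21 * grid))
  expect_equal(dominant_wavenumbers(two, 2), c(21L, 9L))
  expect_equal(dominant_wavenumbers(two, 1), 21L)
  expect_warning(none <- dominant_wavenumbers(pcf_dft(rep(1, X))),
                 "no dominant")
  expect_length(none, 0)
  # equal-power peaks break ties toward the longer wavelength
  tie <- pcf_dft(1 + 0.2 * cos(5 * grid) + 0.2 * cos(13 * grid))
  expect_equal(dominant_wavenumbers(tie, 2), c(5L, 13L))
})

test_that("filtered signal is the closed cosine form", {
  set.seed(29)
  X <- 30
  sp <- pcf_dft(symmetrize_pcf(runif(X / 2 + 1), X = X))
  k1 <- 6
  d <- seq(0, X / 2, by = 0.25)
  expect_equal(filtered_signal(sp, k1, d),
               sp$coefficients[1] +
                 2 * sp$coefficients[k1 + 1] * cos(2 * pi * k1 * d / X))
  expect_equal(filtered_signal(sp, k1, 0),
               sp$coefficients[1] + 2 * sp$coefficients[k1 + 1])
  # period is X / k1
  expect_equal(filtered_signal(sp, k1, d + X / k1),
               filtered_signal(sp, k1, d))
  expect_error(filtered_signal(sp, 0, 1), "k1")
  expect_error(filtered_signal(sp, X, 1), "k1")
})

test_that("wavelengths and bandwidths reproduce the published arithmetic", {
  expect_equal(round(wavelength(17, 100), 2), 5.88)
  expect_equal(wavelength(64, 480), 7.5)
  expect_equal(round(wavelength(40, 390), 2), 9.75)
  expect_error(wavelength(0, 100), "k = 0")
  expect_equal(select_bandwidth(5.88), 6L)
  expect_equal(select_bandwidth(7.5), 8L)   # halves round up
  expect_equal(select_bandwidth(9.75), 10L)
  expect_equal(select_bandwidth(0.5), 1L)
  expect_error(select_bandwidth(0.4), "bandwidth 0")
  expect_error(select_bandwidth(-1), "positive")
})

test_that("the spectral pipeline chains averaging, transform and binning", {
  cfg <- simulation_config(X = 60, s = 3, rho0 = 0.4, N = 10, seed = 41)
  fit <- pcf_spectral(simulate_ensemble(cfg))
  expect_s3_class(fit, "pcf_analysis")
  expect_true(nrow(fit$candidates) >= 1)
  expect_equal(fit$candidates$lambda, 60 / fit$candidates$k)
  expect_equal(fit$candidates$bandwidth,
               as.integer(floor(fit$candidates$lambda + 0.5)))
  expect_equal(fit$bandwidth, fit$candidates$bandwidth[1])
  expect_equal(fit$binned$bandwidth, fit$bandwidth)
  # explicit override wins over the spectral choice
  forced <- pcf_spectral(simulate_ensemble(cfg), bandwidth = 4)
  expect_equal(forced$binned$bandwidth, 4L)
})
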