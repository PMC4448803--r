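test_that("periodic pair-distance wraps around the lattice", {
  expect_equal(periodic_distance(3, 3, 100), 0L)
  expect_equal(periodic_distance(1, 99, 100), 2L)
  expect_equal(periodic_distance(10, 60, 100), 50L)
  expect_equal(periodic_distance(c(1, 2), c(4, 2), 4), c(1L, 0L))
  expect_error(periodic_distance(0, 5, 10), "coordinates")
})

test_that("pair-distance counts match the brute-force oracle exactly", {
  set.seed(101)
  for (rep in 1:15) {
    X <- sample(c(6L, 10L, 16L, 20L), 1)
    n <- sample(2:30, 1)
    sites <- sample.int(X * X, n)
    p <- point_pattern((sites - 1) %% X + 1, (sites - 1) %/% X + 1, X = X)
    for (ax in c("x", "y")) {
      expect_equal(pair_distance_counts(p, ax), brute_counts(p, ax))
      expect_equal(directional_pcf(p, ax), brute_directional_pcf(p, ax))
    }
    # count conservation over unordered pairs
    expect_equal(sum(pair_distance_counts(p, "x")), n * (n - 1) / 2)
  }
})

test_that("counts handle same-coordinate and maximal-distance pairs", {
  p <- point_pattern(c(1, 1), c(1, 3), X = 4)
  expect_equal(pair_distance_counts(p, "x"), c(1, 0, 0))
  expect_equal(pair_distance_counts(p, "y"), c(0, 0, 1))
  Px <- directional_pcf(p, "x")
  expect_gt(Px[1], 0)
  expect_equal(Px[2:3], c(0, 0))
  expect_error(pair_distance_counts(point_pattern(1, 1, X = 4), "x"),
               "fewer than 2")
})

test_that("isotropic signal is the mean of the two directions", {
  set.seed(7)
  p <- csr_pattern(20, 25)
  expect_equal(isotropic_pcf(p),
               (directional_pcf(p, "x") + directional_pcf(p, "y")) / 2)
})

test_that("pair counts are invariant under periodic translation", {
  set.seed(11)
  p <- csr_pattern(16, 20)
  for (shift in c(1, 5, 11)) {
    q <- point_pattern((p$x + shift - 1) %% 16 + 1,
                       (p$y + shift - 1) %% 16 + 1, X = 16)
    expect_equal(pair_distance_counts(q, "x"), pair_distance_counts(p, "x"))
    expect_equal(isotropic_pcf(q), isotropic_pcf(p))
  }
})

test_that("CSR ensembles average to unity at every distance", {
  set.seed(202)
  X <- 20
  pats <- lapply(1:300, function(i) csr_pattern(X, 30))
  pc <- average_pcf(sample_set(pats))
  ok <- abs(pc$values - 1) <= 3 * pc$stderr
  expect_gte(mean(ok), 0.95)
})

test_that("replicate averaging uses the standard error of the mean", {
  set.seed(5)
  a <- csr_pattern(12, 10)
  b <- csr_pattern(12, 14)
  pc <- average_pcf(sample_set(list(a, b)))
  fa <- isotropic_pcf(a)
  fb <- isotropic_pcf(b)
  expect_equal(pc$values, (fa + fb) / 2)
  # N = 2: sqrt(sum of squared deviations / (N(N-1))) reduces to |f1-f2|/2
  expect_equal(pc$stderr, abs(fa - fb) / 2)
  # identical samples give zero error
  same <- average_pcf(sample_set(list(a, a, a)))
  expect_equal(same$stderr, numeric(7))
  # single sample: zero by convention
  one <- average_pcf(sample_set(list(a)))
  expect_equal(one$stderr, numeric(7))
  expect_error(average_pcf(sample_set(list(a, point_pattern(1, 1, 12)))),
               "fewer than 2")
})

test_that("box-kernel binning drops partial bins and is linear", {
  set.seed(31)
  cfg <- simulation_config(X = 100, s = 5, rho0 = 0.3, N = 6, seed = 31)
  pc <- average_pcf(simulate_ensemble(cfg))
  expect_identical(bin_pcf(pc, 1), pc)
  b6 <- bin_pcf(pc, 6)
  expect_equal(length(b6$values), 8L)  # floor(51/6)
  # binning the mean equals averaging the per-sample binned signals
  expect_equal(b6$values,
               vapply(1:8, function(j) {
                 mean(pc$values[((j - 1) * 6 + 1):(j * 6)])
               }, numeric(1)))
  # bin centres sit mid-bin on the distance axis
  expect_equal(b6$centers, (0:7 + 0.5) * 6 - 0.5)
  expect_error(bin_pcf(pc, 52), "exceeds signal support")
  expect_error(bin_pcf(b6, 2), "unbinned")
  # constant signal stays constant under any bandwidth
  flat <- ppcf:::new_pair_correlation(100, 1L, rep(1, 51), rep(0, 51), 2L,
                                      matrix(1, 2, 51))
  expect_equal(bin_pcf(flat, 7)$values, rep(1, 7))
})

test_that("total error is the mean standard error", {
  expect_equal(total_error(c(1, 3))$total_error, 2)
  expect_equal(total_error(rep(0, 5))$total_error, 0)
  set.seed(13)
  pc <- average_pcf(sample_set(lapply(1:4, function(i) csr_pattern(12, 9))))
  es <- total_error(pc)
  expect_equal(es$total_error, mean(pc$stderr))
  expect_equal(es$N, 4L)
  expect_error(total_error(numeric(0)), "empty")
})
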