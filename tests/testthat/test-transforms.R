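test_that("dht1 of a constant has zero imaginary part", {
  a <- dht1(rep(3.7, 12))
  expect_equal(Re(a), rep(3.7, 12))
  expect_equal(Im(a), rep(0, 12), tolerance = 1e-12)
})

test_that("dht1 of cos is the cos + i sin quadrature pair", {
  t <- 0:15
  a <- dht1(cos(2 * pi * t / 16))
  expect_equal(Re(a), cos(2 * pi * t / 16), tolerance = 1e-10)
  expect_equal(Im(a), sin(2 * pi * t / 16), tolerance = 1e-10)
})

test_that("dht1 of a unit impulse matches a direct DFT-mask-IDFT oracle", {
  x <- c(1, 0, 0, 0)
  # brute-force oracle: explicit DFT sums, h = (1, 2, 1, 0) for n = 4
  n <- 4L
  X <- sapply(0:(n - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)))
  h <- c(1, 2, 1, 0)
  expected <- sapply(0:(n - 1), function(t)
    sum(X * h * exp(2i * pi * (0:(n - 1)) * t / n)) / n)
  expect_equal(dht1(x), expected, tolerance = 1e-12)
  # frozen value from the oracle: impulse -> (1, i/2, 0, -i/2)
  expect_equal(dht1(x), c(1 + 0i, 0 + 0.5i, 0 + 0i, 0 - 0.5i),
               tolerance = 1e-12)
})

test_that("dht1 real-part identity and one-sided spectrum hold (properties)", {
  set.seed(11)
  for (n in c(7L, 8L, 16L, 33L)) {
    for (rep in 1:5) {
      x <- rnorm(n)
      a <- dht1(x)
      expect_equal(Re(a), x, tolerance = 1e-9)
      # negative-frequency bins (k > n/2 in 0-based DFT indexing) vanish
      spec <- fft(a)
      neg <- spec[seq_len(n) - 1 > n / 2]
      expect_lt(max(Mod(neg), 0), 1e-9)
    }
  }
})

test_that("dht1 pads, truncates, and validates arguments", {
  x <- rnorm(10)
  expect_equal(Re(dht1(x, 16))[1:10], x, tolerance = 1e-9)
  expect_equal(Re(dht1(x, 16))[11:16], rep(0, 6), tolerance = 1e-9)
  expect_equal(dht1(x, 6), dht1(x[1:6]))
  expect_error(dht1(x, 0), "positive")
  expect_warning(a <- dht1(complex(real = x, imaginary = x)),
                 "imaginary part")
  expect_equal(Re(a), x, tolerance = 1e-9)
})

test_that("dht2 equals sequential 1-D application along both axes", {
  expect_equal(dht2(matrix(0, 20, 20)), matrix(0 + 0i, 20, 20))
  set.seed(4)
  for (i in 1:100) {
    M <- matrix(rnorm(400), 20, 20)
    S <- apply(M, 2, analytic_1d_complex)
    S <- t(apply(S, 1, analytic_1d_complex))
    expect_equal(dht2(M), S, tolerance = 1e-10)
  }
})

test_that("dht2 is linear and checks its input shape", {
  set.seed(5)
  M1 <- matrix(rnorm(400), 20); M2 <- matrix(rnorm(400), 20)
  expect_equal(dht2(M1 + M2), dht2(M1) + dht2(M2), tolerance = 1e-10)
  expect_equal(dht2(3 * M1), 3 * dht2(M1), tolerance = 1e-10)
  expect_error(dht2(matrix(0, 10, 20)), "20 x 20")
})

test_that("dht_features is the flattened modulus of the analytic matrix", {
  expect_identical(as.numeric(dht_features(matrix(0, 20, 20))), rep(0, 400))
  set.seed(6)
  M <- matrix(rnorm(400), 20)
  d <- dht_features(M)
  expect_length(as.numeric(d), 400L)
  expect_true(all(d >= 0))
  A <- dht2(M)
  # element-wise: entry (i, j) at row-major position (i-1)*20 + j
  for (idx in sample(400, 12)) {
    i <- (idx - 1) %/% 20 + 1; j <- (idx - 1) %% 20 + 1
    expect_equal(as.numeric(d)[idx], Mod(A[i, j]), tolerance = 1e-12)
  }
  dsq <- dht_features(M, energy = "squared")
  expect_equal(as.numeric(dsq), as.numeric(d)^2, tolerance = 1e-10)
})

test_that("comparator descriptors have the stated dimensions and zeros map to zeros", {
  Z <- matrix(0, 20, 20)
  for (kind in c("dct", "fft", "dwt"))
    expect_identical(as.numeric(alt_features(Z, kind)), rep(0, 400))
  P0 <- new_profile(matrix(0, 10, 20), source = "synthetic")
  expect_identical(as.numeric(alt_features(P0, "ac", ac_lag = 3L)), rep(0, 60))
  set.seed(7)
  M <- matrix(rnorm(400), 20)
  expect_length(as.numeric(alt_features(M, "dct")), 400L)
  expect_length(as.numeric(alt_features(M, "fft")), 400L)
  expect_length(as.numeric(alt_features(M, "dwt")), 400L)
  expect_length(as.numeric(alt_features(random_profile(30), "ac")), 100L)
})

test_that("DCT concentrates a constant matrix in the DC coefficient", {
  d <- as.numeric(alt_features(matrix(2.5, 20, 20), "dct"))
  expect_equal(d[1], 2.5 * 20, tolerance = 1e-10)  # orthonormal DC gain
  expect_lt(max(abs(d[-1])), 1e-10)
})

test_that("DCT and Haar DWT are orthonormal (energy preserving)", {
  set.seed(8)
  M <- matrix(rnorm(400), 20)
  expect_equal(sum(as.numeric(alt_features(M, "dct"))^2), sum(M^2),
               tolerance = 1e-9)
  expect_equal(sum(as.numeric(alt_features(M, "dwt"))^2), sum(M^2),
               tolerance = 1e-9)
})

test_that("auto-covariance matches the hand-evaluated formula", {
  # single column [1,2,3], g=1: ((1-2)(2-2) + (2-2)(3-2)) / 2 = 0
  P <- new_profile(matrix(rep(c(1, 2, 3), 20), nrow = 3), source = "synthetic")
  d <- as.numeric(alt_features(P, "ac", ac_lag = 1L))
  expect_equal(d, rep(0, 20), tolerance = 1e-12)
  # general oracle on a random profile
  P <- random_profile(12L, seed = 10L)
  g <- 4L
  d <- as.numeric(alt_features(P, "ac", ac_lag = g))
  Pm <- unclass(as.matrix(P))
  for (lag in seq_len(g)) {
    for (j in c(1L, 7L, 20L)) {
      mu <- mean(Pm[, j])
      expect_equal(d[(lag - 1) * 20 + j],
                   sum((Pm[1:(12 - lag), j] - mu) *
                       (Pm[(1 + lag):12, j] - mu)) / (12 - lag),
                   tolerance = 1e-12)
    }
  }
  expect_error(alt_features(random_profile(3), "ac", ac_lag = 5L),
               "smaller ac_lag")
})

test_that("linear transforms are additive and homogeneous", {
  set.seed(9)
  M1 <- matrix(rnorm(400), 20); M2 <- matrix(rnorm(400), 20)
  for (kind in c("dct", "dwt")) {
    f <- function(M) as.numeric(alt_features(M, kind))
    expect_equal(f(M1 + M2), f(M1) + f(M2), tolerance = 1e-10)
    expect_equal(f(-2 * M1), -2 * f(M1), tolerance = 1e-10)
  }
})
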