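test_that("band-pass filter keeps the pass band and rejects DC and fast noise", {
  tr <- 2
  t <- seq(0, by = tr, length.out = 1000)
  amp_ratio <- function(freq) {
    x <- matrix(sin(2 * pi * freq * t), nrow = 1)
    y <- bandpass_filter(x, tr, 0.01, 0.08)
    # compare FFT amplitude at the driving frequency, ignoring edge transients
    keep <- 101:900
    spec_in <- Mod(fft(x[1, keep]))
    spec_out <- Mod(fft(y[1, keep]))
    peak <- which.max(spec_in[2:(length(keep) / 2)]) + 1
    spec_out[peak] / spec_in[peak]
  }
  expect_gt(amp_ratio(0.04), 0.9)  # mid-band preserved
  expect_lt(amp_ratio(0.20), 0.1)  # above the band rejected
  const <- matrix(5, nrow = 2, ncol = 400)
  expect_lt(max(abs(bandpass_filter(const, tr, 0.01, 0.08))), 1e-6)
})

test_that("band-pass filter is zero-phase", {
  tr <- 2
  t <- seq(0, by = tr, length.out = 2000)
  x <- matrix(sin(2 * pi * 0.04 * t), nrow = 1)
  y <- bandpass_filter(x, tr, 0.01, 0.08)
  keep <- 201:1800
  cc <- ccf(as.numeric(x[1, keep]), as.numeric(y[1, keep]), lag.max = 10,
            plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band-pass filter rejects invalid bands and too-short series", {
  x <- matrix(rnorm(200), 2, 100)
  expect_error(bandpass_filter(x, 2, 0.01, 0.3), "Nyquist")
  expect_error(bandpass_filter(x, 2, 0.08, 0.01), "low_hz < high_hz")
  expect_error(bandpass_filter(matrix(rnorm(10), 1, 10), 2, 0.01, 0.08),
               "too short")
})

test_that("nuisance regression leaves residuals orthogonal to covariates", {
  set.seed(1)
  n_t <- 120
  covar <- cbind(drift = seq_len(n_t) / n_t, motion = rnorm(n_t))
  x <- matrix(rnorm(5 * n_t), 5, n_t) + 2 * matrix(covar[, 1], 5, n_t, byrow = TRUE)
  res <- regress_nuisance(x, covar)
  expect_equal(dim(res), dim(x))
  for (j in 1:2) expect_lt(max(abs(res %*% covar[, j])), 1e-8)
  # residual correlation with the covariate is numerically zero
  expect_lt(abs(cor(res[1, ], covar[, 1])), 1e-10)

  # covariate equal to the series itself gives a zero residual
  self <- regress_nuisance(matrix(covar[, 2], 1), covar[, 2])
  expect_lt(max(abs(self)), 1e-10)

  # zero-mean series orthogonal to the covariate passes through unchanged
  z <- sin(2 * pi * seq_len(n_t) / n_t)
  c_orth <- cos(2 * pi * seq_len(n_t) / n_t)
  out <- regress_nuisance(matrix(z, 1), c_orth)
  expect_equal(as.numeric(out), z, tolerance = 1e-10)

  expect_error(regress_nuisance(x, cbind(covar[, 1], covar[, 1])),
               "rank deficient")
})

test_that("correlation matrix matches the textbook Pearson formula", {
  # 3-region, 5-timepoint fixture with hand-computable sums
  x <- rbind(c(1, 2, 3, 4, 5),
             c(2, 1, 4, 3, 6),
             c(5, 4, 3, 2, 1))
  pearson <- function(a, b) {
    n <- length(a)
    num <- sum(a * b) - sum(a) * sum(b) / n
    den <- sqrt((sum(a^2) - sum(a)^2 / n) * (sum(b^2) - sum(b)^2 / n))
    num / den
  }
  r <- correlation_matrix(x)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(r[i, j], pearson(x[i, ], x[j, ]), tolerance = 1e-12)
    }
  }
  expect_true(all(diag(unclass(r)) == 0))
  expect_equal(unclass(r), t(unclass(r)))

  dup <- rbind(a = 1:5, b = 1:5, c = 5:1)
  rd <- correlation_matrix(dup)
  expect_equal(rd[1, 2], 1)
  expect_equal(rd[1, 3], -1)

  expect_error(correlation_matrix(rbind(1:5, rep(2, 5))), "zero-variance")
})

test_that("correlation is invariant under per-region affine rescaling", {
  set.seed(2)
  x <- matrix(rnorm(6 * 50), 6, 50)
  scales <- runif(6, 0.5, 3)
  shifts <- rnorm(6)
  y <- x * scales + shifts
  expect_equal(unclass(correlation_matrix(x)), unclass(correlation_matrix(y)),
               tolerance = 1e-12)
})

test_that("binarization applies the absolute-value threshold rule", {
  r <- matrix(0, 3, 3)
  r[1, 2] <- r[2, 1] <- 0.5
  r[1, 3] <- r[3, 1] <- -0.5
  r[2, 3] <- r[3, 2] <- 0.2
  net4 <- binarize(r, 0.4)
  expect_equal(net4[1, 2], 1)
  expect_equal(net4[1, 3], 1) # strong negative correlation keeps its edge
  expect_equal(net4[2, 3], 0)
  expect_equal(unclass(binarize(r, 0.6))[1, 2], 0)
  # edge kept at exact equality |r| == T
  expect_equal(unclass(binarize(r, 0.5))[1, 2], 1)
  expect_error(binarize(r, 1.2), "inside \\(0, 1\\)")
})

test_that("edge sets are nested as the threshold grows", {
  set.seed(3)
  x <- matrix(rnorm(20 * 60), 20, 60)
  r <- correlation_matrix(x)
  grid <- threshold_grid()
  expect_length(grid, 14)
  prev <- NULL
  for (th in grid) {
    e <- sum(unclass(binarize(r, th))) / 2
    if (!is.null(prev)) expect_lte(e, prev)
    prev <- e
  }
  # edges at a higher threshold are a subset of those at a lower one
  a_low <- unclass(binarize(r, 0.25))
  a_high <- unclass(binarize(r, 0.45))
  expect_true(all(a_low[a_high == 1] == 1))
})

test_that("connectivity bound reproduces 2 ln N", {
  expect_equal(round(connectivity_bound(90)), 9)
  expect_equal(connectivity_bound(90), 2 * log(90), tolerance = 1e-12)
  expect_equal(connectivity_bound(exp(1)), 2, tolerance = 1e-12)
  expect_equal(connectivity_bound(1000), 13.8155, tolerance = 1e-4)
  expect_error(connectivity_bound(1), ">= 2")
})

test_that("the filter-regress-correlate-binarize chain is deterministic", {
  set.seed(4)
  x <- matrix(rnorm(8 * 150), 8, 150)
  covar <- rnorm(150)
  run <- function() {
    y <- bandpass_filter(x, 2, 0.01, 0.08)
    y <- regress_nuisance(y, covar)
    binarize(correlation_matrix(y), 0.25)
  }
  expect_identical(unclass(run()), unclass(run()))
})
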