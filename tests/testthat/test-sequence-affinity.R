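# Sequence-derived affinity tracks and periodicity detection.

test_that("energy conversion is normalized, monotone, and Boltzmann-correct", {
  expect_equal(energy_to_affinity(rep(3.3, 10), 2), rep(1, 10))
  expect_equal(energy_to_affinity(1:5, 0), rep(1, 5))
  k <- energy_to_affinity(c(1, 0), beta = 2)
  expect_equal(k[2] / k[1], exp(2))
  e <- runif(50, -2, 2)
  k2 <- energy_to_affinity(e, 1.5)
  expect_equal(order(k2), order(-e))       # lower energy, higher affinity
  expect_equal(exp(mean(log(k2))), 1)      # geometric mean 1
  expect_error(energy_to_affinity(c(1, NaN)), "finite")
})

test_that("periodic surrogate tracks carry their period", {
  expect_equal(periodic_affinity(100, contrast = 1), rep(1, 100))
  pa <- periodic_affinity(11700, period = 234, contrast = 3)
  expect_equal(range(pa), c(1 / 3, 3), tolerance = 1e-3)
  ac <- stats::acf(pa, lag.max = 400, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[50:400]) + 49L, 234L)
  # default period is the helical-repeat scale
  expect_equal(formals(periodic_affinity)$period, 10.4)
  expect_error(periodic_affinity(100, contrast = 0.5), ">= 1")
})

test_that("PWM scanning scores the consensus at k_site, symmetrically on strands", {
  uni <- matrix(0.25, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  tr <- pwm_affinity("ACGTACGTACGTAAA", uni)
  expect_equal(length(unique(round(tr[1:11], 12))), 1L)
  pwm <- matrix(c(0.97, 0.01, 0.01, 0.01), 4, 6,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  tr2 <- pwm_affinity("GGGGAAAAAAGGGG", pwm, k_site = 5)
  expect_equal(which.max(tr2), 5L)
  expect_equal(max(tr2), 5)
  s <- "ACGTTTACGGATCCATTG"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  pwm3 <- matrix(c(.7, .1, .1, .1, .1, .6, .2, .1, .2, .2, .3, .3, .1, .1, .7, .1),
                 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  nw <- nchar(s) - 4 + 1
  expect_equal(pwm_affinity(s, pwm3)[1:nw],
               rev(pwm_affinity(rc, pwm3)[1:nw]))
  expect_error(pwm_affinity("ACG", pwm3), "shorter than the motif")
})

test_that("tile_repeat concatenates and pads positionally", {
  expect_equal(tile_repeat("ACGT", 3, 2), "ACGTACGTACGTAC")
  expect_equal(tile_repeat("ACGT", 1, 0), "ACGT")
  u <- "GATTACA"
  tiled <- tile_repeat(u, 3)
  chars <- strsplit(tiled, "")[[1]]
  uc <- strsplit(u, "")[[1]]
  for (i in seq_along(chars)) {
    expect_identical(chars[i], uc[(i - 1) %% nchar(u) + 1])
  }
  expect_equal(nchar(tile_repeat(satellite_unit(), 50, 49)), 11749L)
  expect_error(tile_repeat("", 2), "non-empty")
  expect_error(tile_repeat("ACGT", 2, 5), "unit length")
})

test_that("detrending recovers implanted periods despite strong trends", {
  r <- detrend_fourier_period(sin(2 * pi * (1:3000) / 50), 90)
  expect_equal(r$period, 50, tolerance = 2e-3)
  withr::with_seed(42, {
    y <- sin(2 * pi * (1:3000) / 50) + 10 * ((1:3000) / 3000)^3 +
      rnorm(3000, 0, 0.3)
    expect_equal(detrend_fourier_period(y, 90)$period, 50, tolerance = 0.02)
  })
})

test_that("the detected period is stable across polynomial degrees 50-120", {
  withr::with_seed(9, {
    y <- cos(2 * pi * (1:3000) / 181) + 6 * exp(-((1:3000 - 1500) / 700)^2) +
      rnorm(3000, 0, 0.3)
  })
  periods <- vapply(c(50, 70, 90, 120), function(d) {
    detrend_fourier_period(y, d)$period
  }, numeric(1))
  expect_lt(diff(range(periods)), 1e-9)
  expect_equal(periods[1], 181, tolerance = 0.05)
})

test_that("periods across 30-250 bp are recovered within one FFT bin over seeds", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      p <- sample(c(30, 80, 150, 250), 1)
      n <- max(3000, 4 * p)
      y <- cos(2 * pi * (1:n) / p) + rnorm(n, 0, 0.5)   # SNR 2
    })
    n <- length(y)
    est <- detrend_fourier_period(y, 90)$period
    expect_lt(abs(1 / est - 1 / p), 1 / n + 1e-12)
  }
})

test_that("degenerate signals report no period", {
  expect_warning(r <- detrend_fourier_period(rep(2, 1000), 10), "no oscillatory")
  expect_true(is.na(r$period))
})

test_that("GC surrogate landscapes are periodic on tandem repeats", {
  sq <- tile_repeat(satellite_unit(), 6)
  K <- gc_window_affinity(sq, width = 147, beta = 10, smooth = 147)
  U <- 234L
  inner <- K[(U + 1):(4 * U)]
  expect_equal(inner, K[(2 * U + 1):(5 * U)], tolerance = 1e-9)
  expect_equal(exp(mean(log(K))), 1, tolerance = 1e-9)
})
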