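# Cyclic-coordinate fragment analyses on tandem repeats.

test_that("wrapping reduces left ends modulo the unit and preserves lengths", {
  fr <- tibble::tibble(left = c(10, 240, 100), right = c(160, 390, 250))
  w <- wrap_fragments(fr)
  expect_equal(w$left, c(10, 6, 100))
  expect_equal(w$right - w$left, fr$right - fr$left)
  expect_equal(w$length, fr$right - fr$left)
  # pad 0, all within the unit: identity
  fr2 <- tibble::tibble(left = c(3, 50), right = c(120, 200))
  w2 <- wrap_fragments(fr2, unit_length = 234, pad = 0)
  expect_equal(w2$left, fr2$left)
  expect_error(wrap_fragments(tibble::tibble(left = 0, right = 300),
                              unit_length = 200, pad = 49), "longer")
  expect_error(wrap_fragments(tibble::tibble(left = 5, right = 5)), "right > left")
})

test_that("wrapping preserves the fragment count and length distribution", {
  fr <- gen_fragment_set(500, data.frame(position = c(40, 150), sd = 30,
                                         weight = c(0.4, 0.6)), seed = 4)
  raw <- tibble::tibble(left = fr$left + 234, right = fr$right + 234)
  w <- wrap_fragments(raw)
  expect_equal(nrow(w), nrow(fr))
  expect_equal(sort(w$length), sort(fr$length))
})

test_that("end frequencies count one left and one right end per fragment", {
  fr <- tibble::tibble(left = 50, right = 200)
  prof <- end_frequency_profile(fr, unit_length = 234)
  expect_equal(prof$left_count[prof$position == 50], 1L)
  expect_equal(prof$right_count[prof$position == 200], 1L)
  expect_equal(sum(prof$left_count), 1L)
  expect_equal(sum(prof$right_count), 1L)
  # right ends past the unit wrap around
  fr2 <- tibble::tibble(left = 130, right = 280)
  prof2 <- end_frequency_profile(fr2, unit_length = 234)
  expect_equal(prof2$right_count[prof2$position == 280 - 234], 1L)
})

test_that("size selection uses inclusive bounds and is idempotent", {
  lens <- c(140, 145, 150, 151)
  fr <- tibble::tibble(left = 0, right = lens)
  prof <- end_frequency_profile(fr, length_range = c(145, 150), unit_length = 234)
  expect_equal(sum(prof$left_count), 2L)
  pre <- fr[fr$right - fr$left >= 145 & fr$right - fr$left <= 150, ]
  expect_equal(end_frequency_profile(pre, length_range = c(145, 150),
                                     unit_length = 234), prof)
})

test_that("bimodal generators round-trip through the end profile", {
  fr <- gen_fragment_set(10000, data.frame(position = c(50, 130), sd = 2,
                                           weight = c(0.5, 0.5)),
                         length_dist = c(147, 2, 145, 150), seed = 7)
  prof <- end_frequency_profile(fr, length_range = c(145, 150))
  top <- prof$position[order(-prof$left_count)][1:2]
  expect_setequal(top, c(50, 130))
})

test_that("autocorrelation finds comb periods without assuming 10 bp", {
  for (p in c(10, 13)) {
    counts <- rep(0, 234)
    counts[seq(1, 234, by = p)] <- 5
    expect_equal(autocorr_period(counts)$period, p)
  }
  # works on the end-profile tibble directly
  fr <- gen_fragment_set(5000, data.frame(position = 0, sd = 60, weight = 1),
                         seed = 2)
  fr$left <- (fr$left %/% 10) * 10
  fr$right <- fr$left + fr$length
  prof <- end_frequency_profile(fr)
  expect_equal(autocorr_period(prof)$period, 10)
})

test_that("comb periods survive uniform noise across seeds", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      counts <- runif(240, 0, 2.5)             # SNR ~ 2 against the comb
      counts[seq(1, 240, by = 10)] <- counts[seq(1, 240, by = 10)] + 5
    })
    expect_equal(autocorr_period(counts)$period, 10)
  }
})

test_that("generator periods 5-30 bp are recovered end to end", {
  for (p in c(5, 8, 12, 20, 30)) {
    counts <- rep(0, 240)
    counts[seq(1, 240, by = p)] <- 3
    expect_equal(autocorr_period(counts, lag_range = c(3, 60))$period, p)
  }
})

test_that("all-zero counts signal no period", {
  expect_warning(r <- autocorr_period(rep(0, 100)), "zero")
  expect_true(is.na(r$period))
})
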