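# Anchor-centred extraction, normalization, averaging, sorting.

test_that("constant tracks normalize to rows of exactly 1", {
  tr <- list(chr1 = rep(4.2, 9000))
  anchors <- tibble::tibble(chrom = "chr1", position = c(3000, 4500, 6000))
  pm <- extract_profile_matrix(tr, anchors)
  expect_true(all(pm$matrix == 1))
  expect_true(all(pm$average$occupancy == 1))
  expect_equal(pm$n_used, 3L)
})

test_that("anchors with incomplete windows or zero left edges are dropped and counted", {
  tr <- list(chr1 = c(rep(0, 2000), rep(1, 6000)))
  anchors <- tibble::tibble(chrom = "chr1",
                            position = c(1000,   # window leaves the track
                                         3000,   # leftmost value is 0
                                         5000))  # fine
  pm <- extract_profile_matrix(tr, anchors)
  expect_equal(pm$n_used, 1L)
  expect_equal(pm$n_dropped_window, 1L)
  expect_equal(pm$n_dropped_zero, 1L)
  expect_equal(pm$n_used + pm$n_dropped_window + pm$n_dropped_zero,
               nrow(anchors))
})

test_that("minus-strand windows are reversed before averaging", {
  n <- 8000
  tr <- list(chr1 = seq_len(n) / n + 1)        # strictly increasing
  anchors <- tibble::tibble(chrom = "chr1", position = c(4000, 4000),
                            strand = c("+", "-"))
  pm <- extract_profile_matrix(tr, anchors, normalize = FALSE)
  expect_equal(pm$matrix[2, ], rev(pm$matrix[1, ]), ignore_attr = TRUE)
  pm2 <- extract_profile_matrix(tr, anchors, normalize = FALSE,
                                flip_minus_strand = FALSE)
  expect_equal(pm2$matrix[2, ], pm2$matrix[1, ], ignore_attr = TRUE)
})

test_that("averaging commutes with anchor permutation", {
  gp <- gen_phased_track(30000, c(5000, 11000, 17000, 23000), seed = 5)
  a1 <- gp$anchors
  a2 <- a1[c(3, 1, 4, 2), ]
  p1 <- extract_profile_matrix(list(`*` = gp$track), a1)
  p2 <- extract_profile_matrix(list(`*` = gp$track), a2)
  expect_equal(p1$average, p2$average)
})

test_that("implanted anchor-phased oscillations are recovered from the average", {
  gp <- gen_phased_track(60000, seq(4000, 56000, by = 4000), period = 200,
                         amplitude = 0.3, jitter_sd = 5, seed = 21)
  pm <- extract_profile_matrix(list(`*` = gp$track), gp$anchors)
  res <- detrend_fourier_period(pm$average$occupancy, 90)
  expect_equal(res$period, 200, tolerance = 0.05)
})

test_that("sorting is by descending regional mean, stable, and idempotent", {
  mat <- rbind(rep(0.2, 5), rep(0.9, 5), rep(0.5, 5))
  colnames(mat) <- -2:2
  s1 <- sort_matrix_by_mean(mat, region = c(-2, 2))
  expect_equal(unname(s1[, 1]), c(0.9, 0.5, 0.2))
  expect_equal(sort_matrix_by_mean(s1, region = c(-2, 2)), s1)
  withr::with_seed(8, {
    m2 <- matrix(runif(200), 20, 10)
    colnames(m2) <- seq(-450, 450, by = 100)
  })
  s2 <- sort_matrix_by_mean(m2, region = c(-200, 200))
  sel <- as.integer(colnames(s2)) >= -200 & as.integer(colnames(s2)) <= 200
  expect_true(all(diff(rowMeans(s2[, sel])) <= 1e-12))
})

test_that("missing values inside windows count as zero coverage with a warning", {
  tr <- list(chr1 = c(rep(1, 4000), NA, rep(1, 4000)))
  anchors <- tibble::tibble(chrom = "chr1", position = 4000)
  expect_warning(pm <- extract_profile_matrix(tr, anchors), "missing")
  expect_equal(sum(pm$matrix == 0), 1L)
})
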