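# Packaged sequences and seeded generators.

test_that("the satellite unit is the 234-bp consensus", {
  u <- satellite_unit()
  expect_equal(nchar(u), 234L)
  expect_equal(substr(u, 1, 12), "GGACCTGGAATA")
  expect_true(all(strsplit(u, "")[[1]] %in% c("A", "C", "G", "T")))
})

test_that("generators are deterministic per seed and differ across seeds", {
  modes <- data.frame(position = c(50, 130), sd = 2, weight = c(0.5, 0.5))
  f1 <- gen_fragment_set(500, modes, seed = 11)
  f2 <- gen_fragment_set(500, modes, seed = 11)
  f3 <- gen_fragment_set(500, modes, seed = 12)
  expect_identical(f1, f2)
  expect_false(identical(f1$left, f3$left))
  g1 <- gen_phased_track(5000, c(2000, 3500), seed = 3)
  g2 <- gen_phased_track(5000, c(2000, 3500), seed = 3)
  expect_identical(g1, g2)
})

test_that("generators leave the global RNG state untouched", {
  withr::with_seed(99, {
    before <- .Random.seed
    invisible(gen_fragment_set(10, data.frame(position = 0, sd = 1, weight = 1),
                               seed = 5))
    expect_identical(.Random.seed, before)
  })
})

test_that("single-mode zero-sd fragments share one left end", {
  fr <- gen_fragment_set(50, data.frame(position = 77, sd = 0, weight = 1),
                         seed = 1)
  expect_true(all(fr$left == 77))
  expect_true(all(fr$length >= 140 & fr$length <= 155))
})

test_that("generator output passes the consuming module validation", {
  fr <- gen_fragment_set(200, data.frame(position = c(10, 200), sd = 4,
                                         weight = c(0.3, 0.7)), seed = 6)
  w <- wrap_fragments(fr)
  expect_equal(nrow(w), 200L)
  prof <- end_frequency_profile(w)
  expect_equal(sum(prof$left_count), 200L)
})

test_that("boundary models hit their target density within 1%", {
  m <- gen_boundary_model(0.7, N = 4000)
  s <- lattice_solve(m)
  interior <- mean(rowSums(s$coverage)[1501:2500])
  expect_lt(abs(interior - 0.7) / 0.7, 0.01)
  expect_error(gen_boundary_model(1.2), "in \\(0, 1\\)")
})

test_that("a dense boundary model shows at least 5 statistical-positioning peaks", {
  # nucleosome binding constant 3e6 per molar at 1 micromolar free octamer
  m <- lattice_model(4000, species_spec("NCP", 147, binding_constant = 3e6,
                                        concentration = 1e-6))
  s <- lattice_solve(m)
  pk <- find_occupancy_peaks(s$coverage[1:1500, 1])
  expect_gte(nrow(pk), 5L)
})
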