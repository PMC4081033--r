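# Exact solver: hand-checkable partition functions, oracle equivalence,
# closed-form limits, and the model-level invariants.

test_that("two-state lattice reproduces the 1 + a partition function", {
  m <- lattice_model(3, species_spec("A", 3, activity = 1, is_nucleosome = FALSE))
  for (sol in list(lattice_solve(m), brute_force_solve(m))) {
    expect_equal(unname(sol$start_prob[1, 1]), 0.5, tolerance = 1e-12)
    expect_equal(unname(sol$coverage[, 1]), rep(0.5, 3), tolerance = 1e-12)
    expect_equal(sol$log_partition, log(2), tolerance = 1e-12)
  }
})

test_that("zero activity gives an empty lattice and log Z = 0", {
  m <- lattice_model(10, species_spec("A", 3, activity = 0, is_nucleosome = FALSE))
  s <- lattice_solve(m)
  expect_equal(s$free_prob, rep(1, 10))
  expect_equal(unname(s$coverage[, 1]), rep(0, 10))
  expect_identical(s$log_partition, 0)
})

test_that("hard exclusion forbids close pairs: N=7, m=3, V=2 has Z = 1 + 5a", {
  a <- 0.8
  m <- lattice_model(7, species_spec("A", 3, activity = a, is_nucleosome = FALSE),
                     interactions = list(hard_exclusion("A", "A", 2)))
  for (sol in list(lattice_solve(m), brute_force_solve(m))) {
    expect_equal(sol$log_partition, log(1 + 5 * a), tolerance = 1e-12)
    # without the exclusion the pairs (0,3), (0,4), (1,4) would add 3 a^2
    expect_equal(sum(sol$start_prob[, 1]), 5 * a / (1 + 5 * a),
                 tolerance = 1e-12)
  }
})

test_that("solver matches enumeration on the mixed two-species instance", {
  m <- lattice_model(
    14,
    list(species_spec("A", 4, activity = 1.2, unwrap = unwrap_spec(2),
                      is_nucleosome = FALSE),
         species_spec("B", 2, activity = 0.8, is_nucleosome = FALSE)),
    interactions = list(contact_cooperativity("A", "A", 5),
                        hard_exclusion("A", "B", 2)))
  expect_solution_agreement(lattice_solve(m), brute_force_solve(m))
})

test_that("solver matches enumeration across seeded random instances", {
  for (seed in 1:40) {
    m <- random_small_model(seed)
    expect_solution_agreement(lattice_solve(m),
                              brute_force_solve(m, max_configs = 1e7))
  }
})

test_that("marginals are normalized: free + total coverage = 1 everywhere", {
  for (seed in c(3, 11, 27)) {
    s <- lattice_solve(random_small_model(seed))
    expect_lt(max(abs(s$free_prob + rowSums(s$coverage) - 1)), 1e-9)
    expect_true(all(s$coverage >= -1e-12 & s$coverage <= 1 + 1e-12))
    expect_true(all(s$free_prob >= -1e-12 & s$free_prob <= 1 + 1e-12))
  }
})

test_that("palindromic landscapes give mirror-symmetric solutions", {
  # mirror symmetry maps a frame starting at n (1-based) to one starting at
  # N - m + 2 - n, so the affinity must be palindromic in frame starts
  N <- 200L; m_fp <- 5L
  withr::with_seed(14, half <- runif(98, 0.2, 2))
  K <- numeric(N)
  for (n in 1:98) {
    K[n] <- half[n]
    K[N - m_fp + 2L - n] <- half[n]
  }
  mod <- lattice_model(N, species_spec("A", m_fp, activity = 0.8,
                                       is_nucleosome = FALSE),
                       affinity = list(A = K),
                       interactions = list(contact_cooperativity("A", "A", 2)))
  s <- lattice_solve(mod)
  expect_equal(unname(s$coverage[, 1]), rev(unname(s$coverage[, 1])),
               tolerance = 1e-9)
  expect_equal(s$free_prob, rev(s$free_prob), tolerance = 1e-9)
})

test_that("homogeneous coverage is non-decreasing in activity", {
  covs <- vapply(c(0.1, 0.3, 1, 3, 10), function(a) {
    s <- lattice_solve(lattice_model(300, species_spec("A", 7, activity = a,
                                                       is_nucleosome = FALSE)))
    mean(s$coverage[, 1])
  }, numeric(1))
  expect_true(all(diff(covs) > 0))
})

test_that("hard-wall oscillation period approaches the footprint at high activity", {
  m <- lattice_model(600, species_spec("A", 10, activity = 1000,
                                       is_nucleosome = FALSE))
  s <- lattice_solve(m)
  pk <- find_occupancy_peaks(s$coverage[1:300, 1], min_separation = 5)
  spacings <- diff(pk$position)
  expect_true(all(spacings >= 10 & spacings <= 12))
  expect_lt(mean(spacings), 11)
})

test_that("cyclic boundary matches enumeration, including wrap interactions", {
  m <- lattice_model(9, species_spec("A", 3, activity = 1.5, is_nucleosome = FALSE),
                     interactions = list(interaction_rule("A", "A", c(0.2, 3, 1, 0.5, 2))),
                     boundary = "cyclic")
  expect_solution_agreement(lattice_solve(m), brute_force_solve(m))
  # translational symmetry of a homogeneous ring
  s <- lattice_solve(lattice_model(12, species_spec("A", 4, activity = 0.7,
                                                    is_nucleosome = FALSE),
                                   boundary = "cyclic"))
  expect_lt(diff(range(s$coverage[, 1])), 1e-10)
})

test_that("invalid models are rejected with informative errors", {
  sp <- species_spec("A", 20, activity = 1, is_nucleosome = FALSE)
  expect_error(lattice_model(10, sp), "shorter than the largest footprint")
  expect_error(interaction_rule("A", "A", c(1, -0.5)), "non-negative")
  expect_error(
    lattice_model(6, species_spec("A", 3, activity = 1, is_nucleosome = FALSE),
                  interactions = list(interaction_rule("A", "A", c(rep(0.5, 7), 2))),
                  boundary = "cyclic"),
    "smaller than N")
  expect_error(unwrap_spec(-1), "non-negative")
  expect_error(species_spec("A", 5, activity = 1,
                            unwrap = unwrap_spec(5), is_nucleosome = FALSE),
               "smaller than the footprint")
})

test_that("cyclic boundaries reject linker-cap rules in the DP solver", {
  m <- lattice_model(
    12,
    list(species_spec("N", 4, activity = 1, is_nucleosome = TRUE),
         species_spec("L", 2, activity = 1, is_nucleosome = FALSE)),
    linker_cap = linker_cap_rule("L", "N"),
    boundary = "cyclic")
  expect_error(lattice_solve(m), "cyclic")
  # the enumeration oracle still handles the combination
  b <- brute_force_solve(m)
  expect_lt(max(abs(b$free_prob + rowSums(b$coverage) - 1)), 1e-9)
})

test_that("enumeration refuses oversized instances with a size estimate", {
  m <- lattice_model(60, species_spec("A", 2, activity = 1, is_nucleosome = FALSE))
  expect_error(brute_force_solve(m, max_configs = 1e4), "configurations")
})

test_that("linker-cap rule caps bound linkers per nucleosome", {
  # one nucleosome slot, abundant linker: without the cap the lattice would
  # fill with linkers; with cap = 1 and contact anchoring at most one linker
  # binds on each side of the nucleosome
  m <- lattice_model(
    16,
    list(species_spec("N", 6, activity = 50, is_nucleosome = TRUE),
         species_spec("L", 2, activity = 50, is_nucleosome = FALSE)),
    linker_cap = linker_cap_rule("L", "N", cap = 1, vicinity = 0,
                                 allow_free_binding = FALSE))
  b <- brute_force_solve(m)
  s <- lattice_solve(m)
  expect_solution_agreement(s, b)
  n_nuc <- sum(s$start_prob[, "N"])
  n_l <- sum(s$start_prob[, "L"])
  expect_lte(n_l, 2 * n_nuc + 1e-9)
})

test_that("McGhee-von Hippel density solves the closed forms", {
  expect_equal(mcghee_von_hippel_density(1, 1), 0.5, tolerance = 1e-10)
  expect_equal(mcghee_von_hippel_density(1, 3), 0.75, tolerance = 1e-10)
  # m = 2: nu (1 - nu) = a (1 - 2 nu)^2 rearranges to
  # (4a + 1) nu^2 - (4a + 1) nu + a = 0; the physical root is the smaller one
  a <- 0.5
  roots <- polyroot(c(a, -(4 * a + 1), 4 * a + 1))
  nu_exact <- min(Re(roots[abs(Im(roots)) < 1e-9]))
  expect_equal(mcghee_von_hippel_density(2, a), nu_exact, tolerance = 1e-9)
  # inversion round trip
  expect_equal(147 * mcghee_von_hippel_density(
    147, mcghee_von_hippel_activity(147, 0.7)), 0.7, tolerance = 1e-10)
})

test_that("interior of a long lattice converges to the isotherm", {
  for (mfp in c(10, 147)) {
    a <- mcghee_von_hippel_activity(mfp, 0.55)
    s <- lattice_solve(lattice_model(3000, species_spec("A", mfp, activity = a,
                                                        is_nucleosome = FALSE)))
    interior <- mean(rowSums(s$coverage)[1201:1800])
    expect_lt(abs(interior - 0.55), 1e-4)
  }
})

test_that("solution accessors tidy and glance are consistent", {
  m <- lattice_model(50, species_spec("A", 5, activity = 0.5, is_nucleosome = FALSE))
  s <- lattice_solve(m)
  td <- tidy(s)
  expect_equal(nrow(td), 50)
  expect_equal(td$coverage, unname(s$coverage[, 1]))
  gl <- glance(s)
  expect_equal(gl$log_partition, s$log_partition)
})
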