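# Shared fixtures: seeded random small lattice instances and the
# solver-vs-enumeration comparison used throughout the suite.

# Relative agreement between the DP solver and the enumeration oracle.
# Marginals are compared entry-wise relative to their magnitude (with a
# floor well below any probability of interest, so that strongly
# suppressed entries are compared absolutely).
expect_solution_agreement <- function(a, b, tol = 1e-9, floor = 1e-3) {
  rel <- function(x, y) max(abs(x - y) / pmax(abs(y), floor))
  expect_lt(rel(a$coverage, b$coverage), tol)
  expect_lt(rel(a$start_prob, b$start_prob), tol)
  expect_lt(rel(a$free_prob, b$free_prob), tol)
  expect_lt(abs(a$log_partition - b$log_partition), tol)
}

# Random enumerable instance. Drawn features: 1-2 species with footprints
# 2-5, optional unwrapping, optional affinity tracks, optional contact /
# exclusion / general interactions, optional linker-cap rule, and (when no
# cap is present) an occasional cyclic boundary.
random_small_model <- function(seed) {
  withr::with_seed(seed, {
    nsp <- sample(1:2, 1)
    use_unwrap <- runif(1) < 0.4
    boundary_cyclic <- runif(1) < 0.25
    N <- if (boundary_cyclic) sample(8:10, 1)
         else sample(if (use_unwrap) 8:11 else 9:13, 1)
    fps <- sample(3:5, nsp, replace = TRUE)
    ids <- c("A", "B")[seq_len(nsp)]
    species <- lapply(seq_len(nsp), function(i) {
      un <- if (use_unwrap) {
        # keep covered lengths >= 2 so instances stay enumerable
        unwrap_spec(min(sample(1:2, 1), fps[i] - 2L),
                    per_bp_penalty = runif(1, 0.5, 1.2))
      }
      species_spec(ids[i], fps[i], activity = runif(1, 0.2, 2), unwrap = un,
                   is_nucleosome = FALSE)
    })
    affinity <- list()
    if (runif(1) < 0.5) {
      for (i in seq_len(nsp)) {
        if (runif(1) < 0.7) affinity[[ids[i]]] <- runif(N, 0, 2)
      }
    }
    interactions <- list()
    if (runif(1) < 0.6) {
      g1 <- sample(ids, 1); g2 <- sample(ids, 1)
      interactions <- list(switch(sample(3, 1),
        contact_cooperativity(g1, g2, sample(c(0.3, 2, 5), 1)),
        hard_exclusion(g1, g2, sample(2:3, 1)),
        interaction_rule(g1, g2, runif(sample(2:4, 1), 0, 3))
      ))
    }
    cap <- NULL
    if (nsp == 2L && fps[1] != fps[2] && runif(1) < 0.4) {
      nuc <- ids[which.max(fps)]; lnk <- ids[which.min(fps)]
      cap <- linker_cap_rule(lnk, nuc, cap = sample(1:2, 1),
                             vicinity = sample(0:2, 1),
                             allow_free_binding = runif(1) < 0.5)
    }
    boundary <- if (is.null(cap) && boundary_cyclic) "cyclic" else "hard_wall"
    lattice_model(N, species, affinity = affinity,
                  interactions = interactions, linker_cap = cap,
                  boundary = boundary)
  })
}

# Deterministic peak ladder with seeded Gaussian jitter.
jittered_ladder <- function(n_peaks, spacing, sd, seed) {
  withr::with_seed(seed, {
    pos <- (seq_len(n_peaks) - 1) * spacing + 100 +
      round(stats::rnorm(n_peaks, 0, sd))
    sort(pos)
  })
}
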