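# Exact equilibrium solver: forward/backward dynamic programming over
# covered-end positions, with finite-range pairwise weights handled through
# an explicit gap window of width rmax and a cumulative "far" channel.

RESCALE_EVERY <- 64L
RESCALE_LIMIT <- 1e250

# Core linear engine.
#
# NL:       domain length (covered positions 0 .. NL-1, ends 0 .. NL)
# W:        list per class of per-start weights over the domain (index s+1)
# phantoms: NULL, or list(left = species idx, right = species idx) marking a
#           conditioning particle of that species ending at 0 / starting at
#           NL (used by the cyclic driver; requires no cap rule, so states
#           are species indices there)
# Returns log-partition and, if want_marginals, the matrix p[s+1, j] of
# marginal placement probabilities per class.
run_engine <- function(cmp, NL, W, phantoms = NULL, want_marginals = TRUE,
                       start_allowed = NULL) {
  S <- cmp$S; C <- cmp$C
  rmax <- cmp$rmax
  lens <- cmp$cls_len
  trans <- cmp$trans
  end_legal <- cmp$end_legal
  with_phantom <- !is.null(phantoms)
  if (with_phantom && cmp$has_cap) {
    abort("internal: phantom conditioning is incompatible with a linker-cap rule")
  }
  stL <- if (with_phantom) match(phantoms$left, cmp$states$g) else NA_integer_
  gR <- if (with_phantom) phantoms$right else NA_integer_

  f <- matrix(0, NL + 1L, S)
  if (with_phantom) f[1L, stL] <- 1
  cfar <- numeric(S)
  empty_w <- if (with_phantom) 0 else 1   # weight of the empty prefix
  scale_f <- 0
  # log-space snapshots of the inbound sums, taken at computation time so
  # later rescaling cannot underflow them (they are only read back when the
  # marginals are assembled)
  Ilog <- if (want_marginals) {
    lapply(seq_len(C), function(j) matrix(-Inf, max(NL, 1L), S))
  }

  feasible <- function(j, s0) {
    s0 + lens[j] <= NL && W[[j]][s0 + 1L] > 0 &&
      (is.null(start_allowed) || start_allowed[s0 + 1L])
  }

  # Single-state fast path: one species, no finite-range window. All classes
  # then share the same inbound sum, so the class loop vectorises.
  if (S == 1L && rmax == 0L && !with_phantom && is.null(start_allowed) &&
      NL > 0L) {
    return(run_engine_fast(cmp, NL, W, want_marginals))
  }

  if (NL > 0L) for (s0 in 0:(NL - 1L)) {
    if (s0 - rmax - 1L >= 0L) cfar <- cfar + f[s0 - rmax, ]
    lo <- max(0L, s0 - rmax)
    rows <- (lo + 1L):(s0 + 1L)            # ends e = lo .. s0
    wtail <- (rmax - (s0 - lo) + 1L):(rmax + 1L)
    for (j in seq_len(C)) {
      if (!feasible(j, s0)) next
      acc <- numeric(S)
      if (!with_phantom) acc[cmp$start_dest[j]] <- empty_w
      for (st in seq_len(S)) {
        tr <- trans[[st]][[j]]
        if (tr$far_dest > 0L && cfar[st] != 0) {
          acc[tr$far_dest] <- acc[tr$far_dest] + cfar[st]
        }
        fs <- f[rows, st]
        if (all(fs == 0)) next
        for (en in tr$entries) {
          v <- sum(fs * en$wrev[wtail])
          if (v != 0) acc[en$dest] <- acc[en$dest] + v
        }
      }
      if (want_marginals) Ilog[[j]][s0 + 1L, ] <- log(acc) + scale_f
      epos <- s0 + lens[j]
      f[epos + 1L, ] <- f[epos + 1L, ] + acc * W[[j]][s0 + 1L]
    }
    if (s0 %% RESCALE_EVERY == 0L) {
      mx <- max(f)
      if (mx > RESCALE_LIMIT) {
        f <- f / mx; cfar <- cfar / mx; empty_w <- empty_w / mx
        scale_f <- scale_f + log(mx)
      }
    }
  }

  # close the partition sum. In phantom mode the row e = 0 holds exactly the
  # left-phantom seed (no real particle can end at 0), so the empty-interior
  # term between the two phantoms is covered by the same closing sum.
  if (!with_phantom) {
    Z_stored <- empty_w + sum(f %*% end_legal)
  } else {
    gap <- NL - (0:NL)
    near <- gap <= rmax
    Z_stored <- 0
    for (st in seq_len(S)) {
      wv <- rep(1, NL + 1L)
      if (any(near)) wv[near] <- cmp$wpair[cmp$states$g[st], gR, gap[near] + 1L]
      Z_stored <- Z_stored + sum(f[, st] * wv)
    }
  }
  logZ <- log(Z_stored) + scale_f
  if (!want_marginals || NL == 0L) {
    return(list(logZ = logZ, p = matrix(0, max(NL, 1L), C)))
  }

  # backward pass ------------------------------------------------------------
  b <- matrix(0, NL + 1L, S)
  blog <- matrix(-Inf, NL + 1L, S)   # log snapshot for the marginal assembly
  endw <- 1
  scale_b <- 0
  Gcur <- matrix(0, C, S)     # suffix sums for the far channel
  gptr <- NL + 1L             # terms s0 >= gptr are folded into Gcur
  Wvecs <- W
  for (e in NL:0) {
    xtarget <- e + rmax + 1L
    while (gptr > xtarget) {
      gptr <- gptr - 1L
      s0 <- gptr
      if (s0 <= NL - 1L) {
        for (j in seq_len(C)) {
          if (!feasible(j, s0)) next
          Gcur[j, ] <- Gcur[j, ] + Wvecs[[j]][s0 + 1L] * b[s0 + lens[j] + 1L, ]
        }
      }
    }
    for (st in seq_len(S)) {
      val <- if (!with_phantom) end_legal[st] * endw else {
        gap <- NL - e
        (if (gap <= rmax) cmp$wpair[cmp$states$g[st], gR, gap + 1L] else 1) * endw
      }
      for (j in seq_len(C)) {
        tr <- trans[[st]][[j]]
        if (tr$far_dest > 0L) val <- val + Gcur[j, tr$far_dest]
        smax <- min(NL - lens[j], e + rmax)
        if (smax >= e) {
          svec <- e:smax
          wj <- Wvecs[[j]][svec + 1L]
          if (any(wj > 0)) {
            brows <- svec + lens[j] + 1L
            ok <- if (is.null(start_allowed)) TRUE else start_allowed[svec + 1L]
            wj <- wj * ok
            for (en in tr$entries) {
              wseg <- en$w[svec - e + 1L]
              if (all(wseg == 0)) next
              val <- val + sum(wseg * wj * b[brows, en$dest])
            }
          }
        }
      }
      b[e + 1L, st] <- val
      blog[e + 1L, st] <- log(val) + scale_b
    }
    if (e %% RESCALE_EVERY == 0L) {
      mx <- max(b)
      if (mx > RESCALE_LIMIT) {
        b <- b / mx; Gcur <- Gcur / mx; endw <- endw / mx
        scale_b <- scale_b + log(mx)
      }
    }
  }

  # marginals ---------------------------------------------------------------
  p <- matrix(0, NL, C)
  for (j in seq_len(C)) {
    svec <- 0:(NL - 1L)
    keep <- svec + lens[j] <= NL
    wj <- Wvecs[[j]][svec + 1L]
    tot <- numeric(NL)
    for (st in seq_len(S)) {
      Icol <- Ilog[[j]][, st]
      if (all(Icol == -Inf)) next
      bcol <- rep(-Inf, NL)
      bcol[keep] <- blog[svec[keep] + lens[j] + 1L, st]
      tot <- tot + exp(Icol + log(wj) + bcol - logZ)
    }
    p[, j] <- tot
  }
  list(logZ = logZ, p = p)
}

# Vectorised engine for the one-species, contact-range-only case.
run_engine_fast <- function(cmp, NL, W, want_marginals) {
  C <- cmp$C
  lens <- cmp$cls_len
  w00 <- cmp$wpair[1L, 1L, 1L]
  Wmat <- do.call(cbind, W)                # NL x C
  f <- numeric(NL + 1L)                    # index e + 1
  cfar <- 0
  empty_w <- 1
  scale_f <- 0
  Iv <- rep(-Inf, NL)
  feas_to <- NL - lens                     # max s0 per class
  for (s0 in 0:(NL - 1L)) {
    if (s0 >= 1L) cfar <- cfar + f[s0]
    acc <- empty_w + cfar + f[s0 + 1L] * w00
    if (acc != 0) {
      ws <- Wmat[s0 + 1L, ]
      ok <- which(ws > 0 & s0 <= feas_to)
      if (length(ok)) {
        idx <- s0 + lens[ok] + 1L
        f[idx] <- f[idx] + acc * ws[ok]
        Iv[s0 + 1L] <- log(acc) + scale_f
      }
    }
    if (s0 %% RESCALE_EVERY == 0L) {
      mx <- max(f)
      if (mx > RESCALE_LIMIT) {
        f <- f / mx; cfar <- cfar / mx; empty_w <- empty_w / mx
        scale_f <- scale_f + log(mx)
      }
    }
  }
  logZ <- log(empty_w + sum(f)) + scale_f
  if (!want_marginals) return(list(logZ = logZ, p = matrix(0, NL, C)))

  b <- numeric(NL + 1L)
  blog <- rep(-Inf, NL + 1L)
  endw <- 1
  scale_b <- 0
  Gsum <- 0
  for (e in NL:0) {
    if (e + 1L <= NL - 1L) {               # fold s0 = e + 1 into the far sum
      s0 <- e + 1L
      ok <- which(s0 <= feas_to)
      if (length(ok)) Gsum <- Gsum + sum(Wmat[s0 + 1L, ok] * b[s0 + lens[ok] + 1L])
    }
    near <- 0
    if (e <= NL - 1L) {
      ok <- which(e <= feas_to)
      if (length(ok)) near <- w00 * sum(Wmat[e + 1L, ok] * b[e + lens[ok] + 1L])
    }
    val <- endw + Gsum + near
    b[e + 1L] <- val
    blog[e + 1L] <- log(val) + scale_b
    if (e %% RESCALE_EVERY == 0L) {
      mx <- max(b)
      if (mx > RESCALE_LIMIT) {
        b <- b / mx; Gsum <- Gsum / mx; endw <- endw / mx
        scale_b <- scale_b + log(mx)
      }
    }
  }

  p <- matrix(0, NL, C)
  svec <- 0:(NL - 1L)
  for (j in seq_len(C)) {
    keep <- svec + lens[j] <= NL
    bcol <- rep(-Inf, NL)
    bcol[keep] <- blog[svec[keep] + lens[j] + 1L]
    p[, j] <- exp(Iv + log(Wmat[, j]) + bcol - logZ)
  }
  list(logZ = logZ, p = p)
}

#' Solve a lattice binding model exactly
#'
#' Computes the exact Boltzmann-ensemble marginals of the model by dynamic
#' programming: every configuration (a set of bound particles with
#' non-overlapping covered stretches) carries the product of its per-particle
#' weights `a(g) K(n, g) eps^(h1+h2)`, pairwise weights `w(L, g1, g2)`
#' between nearest covered neighbours, and the linker-cap legality factor;
#' marginal start probabilities and per-position coverage follow from the
#' forward-backward recursions. No sampling is involved and the result is
#' deterministic.
#'
#' Under a cyclic boundary the solver conditions on the bound particle with
#' the smallest covered start on the ring and reduces each case to a linear
#' problem between two copies of that particle; the cost grows with
#' `N^2`, so rings are intended for repeat-scale (hundreds to a few thousand
#' bp) lattices. A cyclic boundary cannot be combined with a linker-cap rule.
#'
#' @param model A [lattice_model()].
#' @return A `lattice_solution` with components `start_prob` (N x species
#'   matrix of expected frame starts per position), `coverage` (N x species
#'   matrix, `c(g, n)`), `free_prob` (length-N vector), and `log_partition`.
#' @examples
#' m <- lattice_model(12, species_spec("rod", 4, activity = 0.5))
#' sol <- lattice_solve(m)
#' head(tidy(sol))
#' @export
lattice_solve <- function(model) {
  stopifnot(inherits(model, "lattice_model"))
  cmp <- compile_model(model)
  if (!cmp$cyclic) {
    eng <- run_engine(cmp, cmp$N, cmp$cls_W, want_marginals = TRUE)
    return(assemble_solution(model, cmp, eng$p, eng$logZ, cyclic = FALSE))
  }
  if (cmp$has_cap) {
    abort("cyclic boundaries cannot be combined with a linker-cap rule; use brute_force_solve() for small instances",
          class = "nucspacing_error")
  }
  solve_cyclic(model, cmp)
}

# Cyclic driver: condition on the particle with the smallest covered start.
solve_cyclic <- function(model, cmp) {
  N <- cmp$N; C <- cmp$C
  branches <- list()
  logw <- numeric(0)
  for (j1 in seq_len(C)) {
    W1 <- cmp$cls_W[[j1]]
    l1 <- cmp$cls_len[j1]
    for (cs1 in 0:(N - 1L)) {
      if (W1[cs1 + 1L] == 0) next
      branches[[length(branches) + 1L]] <- c(j1, cs1)
      logw[length(branches)] <- NA_real_
    }
  }
  if (!length(branches)) {
    p0 <- matrix(0, N, C)
    return(assemble_solution(model, cmp, p0, 0, cyclic = TRUE))
  }

  branch_setup <- function(j1, cs1) {
    l1 <- cmp$cls_len[j1]
    ce1 <- cs1 + l1
    NL <- N - l1
    Wcut <- vector("list", C)
    for (j in seq_len(C)) {
      v <- numeric(max(NL, 1L))
      if (NL > 0L) {
        pidx <- 0:(NL - 1L)
        ring <- (ce1 + pidx) %% N
        v[pidx + 1L] <- cmp$cls_W[[j]][ring + 1L]
        v[(ce1 + pidx) >= N] <- 0    # minimality of the anchor's start
      }
      Wcut[[j]] <- v
    }
    list(NL = NL, W = Wcut, g1 = cmp$cls_g[j1], ce1 = ce1)
  }

  # pass 1: branch partition sums
  for (bidx in seq_along(branches)) {
    j1 <- branches[[bidx]][1L]; cs1 <- branches[[bidx]][2L]
    bs <- branch_setup(j1, cs1)
    eng <- run_engine(cmp, bs$NL, bs$W,
                      phantoms = list(left = bs$g1, right = bs$g1),
                      want_marginals = FALSE)
    logw[bidx] <- log(cmp$cls_W[[j1]][cs1 + 1L]) + eng$logZ
  }
  mx <- max(0, logw)   # 0 = empty-ring term
  logZ <- mx + log(exp(0 - mx) + sum(exp(logw - mx)))

  # pass 2: marginals
  p_ring <- matrix(0, N, C)
  for (bidx in seq_along(branches)) {
    j1 <- branches[[bidx]][1L]; cs1 <- branches[[bidx]][2L]
    bprob <- exp(logw[bidx] - logZ)
    if (bprob < .Machine$double.eps^2) next
    bs <- branch_setup(j1, cs1)
    p_ring[cs1 + 1L, j1] <- p_ring[cs1 + 1L, j1] + bprob
    if (bs$NL > 0L) {
      eng <- run_engine(cmp, bs$NL, bs$W,
                        phantoms = list(left = bs$g1, right = bs$g1),
                        want_marginals = TRUE)
      for (j in seq_len(C)) {
        pj <- eng$p[, j]
        nz <- which(pj > 0)
        for (i in nz) {
          ring <- (bs$ce1 + i - 1L) %% N
          p_ring[ring + 1L, j] <- p_ring[ring + 1L, j] + bprob * pj[i]
        }
      }
    }
  }
  assemble_solution(model, cmp, p_ring, logZ, cyclic = TRUE)
}

# Turn per-class placement marginals into the user-facing solution object.
assemble_solution <- function(model, cmp, p, logZ, cyclic) {
  N <- cmp$N; G <- cmp$G
  coverage <- matrix(0, N, G, dimnames = list(NULL, cmp$ids))
  start_prob <- matrix(0, N, G, dimnames = list(NULL, cmp$ids))
  for (j in seq_len(cmp$C)) {
    g <- cmp$cls_g[j]; u <- cmp$cls_u[j]; len <- cmp$cls_len[j]
    pj <- p[, j]
    nz <- pj > 0
    if (!any(nz)) next
    # coverage via difference array (arcs wrap on the ring)
    dif <- numeric(2L * N + 1L)
    s0 <- which(nz) - 1L
    vals <- pj[nz]
    for (i in seq_along(s0)) {
      dif[s0[i] + 1L] <- dif[s0[i] + 1L] + vals[i]
      dif[s0[i] + len + 1L] <- dif[s0[i] + len + 1L] - vals[i]
    }
    cum <- cumsum(dif[seq_len(2L * N)])
    cov_j <- cum[seq_len(N)]
    if (cyclic) cov_j <- cov_j + cum[N + seq_len(N)]
    coverage[, g] <- coverage[, g] + cov_j
    # frame-start marginals: distribute each placement over its h1 splits
    Ksum <- cmp$cls_Ksum[[j]]
    Kg <- cmp$K[[g]]
    for (h1 in 0:u) {
      if (cyclic) {
        n0 <- (s0 - h1) %% N
        frac <- Kg[n0 + 1L] / Ksum[s0 + 1L]
        add <- vals * frac
        for (i in seq_along(n0)) {
          start_prob[n0[i] + 1L, g] <- start_prob[n0[i] + 1L, g] + add[i]
        }
      } else {
        ok <- s0 - h1 >= 0L
        if (!any(ok)) next
        n0 <- s0[ok] - h1
        frac <- Kg[n0 + 1L] / Ksum[s0[ok] + 1L]
        add <- vals[ok] * frac
        start_prob[cbind(n0 + 1L, g)] <- start_prob[cbind(n0 + 1L, g)] + add
      }
    }
  }
  free_prob <- 1 - rowSums(coverage)
  structure(
    list(start_prob = start_prob, coverage = coverage, free_prob = free_prob,
         log_partition = logZ, N = N, species = cmp$ids,
         boundary = model$boundary, method = "dynamic_programming"),
    class = "lattice_solution"
  )
}

#' @export
print.lattice_solution <- function(x, ...) {
  cat(sprintf("<lattice_solution> N = %d bp (%s), log Z = %.6g\n",
              x$N, x$boundary, x$log_partition))
  for (g in x$species) {
    cat(sprintf("  %s: mean coverage %.4f, expected particles %.3f\n",
                g, mean(x$coverage[, g]), sum(x$start_prob[, g])))
  }
  invisible(x)
}

#' @describeIn lattice_solve Long-format view of a solution: one row per
#'   position and species with start probability and coverage.
#' @param x A `lattice_solution`.
#' @param ... Unused.
#' @export
tidy.lattice_solution <- function(x, ...) {
  out <- tidyr::expand_grid(species = x$species, position = seq_len(x$N))
  out$start_prob <- unlist(lapply(x$species, function(g) x$start_prob[, g]),
                           use.names = FALSE)
  out$coverage <- unlist(lapply(x$species, function(g) x$coverage[, g]),
                         use.names = FALSE)
  out
}

#' @describeIn lattice_solve One-row summary of a solution.
#' @export
glance.lattice_solution <- function(x, ...) {
  tibble(
    N = x$N, boundary = x$boundary, log_partition = x$log_partition,
    total_particles = sum(x$start_prob),
    mean_free = mean(x$free_prob)
  )
}
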