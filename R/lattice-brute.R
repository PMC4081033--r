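# Exhaustive enumeration oracle. Deliberately independent of the
# dynamic-programming solver: it expands every placement (species, frame
# start, unwrapping split), walks every configuration, applies pair weights
# and the linker-cap rule declaratively on the full token sequence, and
# tallies the marginals by direct summation.

#' Solve a lattice model by explicit enumeration
#'
#' Enumerates every configuration of non-overlapping bound particles
#' (including all unwrapping splits), multiplies out particle, pair and
#' legality weights, and sums the marginals directly. The contract is
#' identical to [lattice_solve()]; this is the reference implementation used
#' to validate the dynamic-programming solver on small instances.
#'
#' @param model A [lattice_model()].
#' @param max_configs Guard on the estimated configuration count (an upper
#'   bound that ignores interaction weights); enumeration refuses instances
#'   above it.
#' @return A `lattice_solution` (with `method = "enumeration"`).
#' @export
brute_force_solve <- function(model, max_configs = 1e7) {
  stopifnot(inherits(model, "lattice_model"))
  N <- model$N
  sp <- model$species
  G <- length(sp)
  ids <- names(sp)
  cyc <- model$boundary == "cyclic"

  # placement table ----------------------------------------------------------
  pg <- integer(0); pn <- integer(0); ph1 <- integer(0); ph2 <- integer(0)
  pcs <- integer(0); plen <- integer(0); pw <- numeric(0)
  for (g in seq_len(G)) {
    s <- sp[[g]]
    m <- s$footprint
    hm <- if (is.null(s$unwrap)) 0L else s$unwrap$h_max
    eps <- if (is.null(s$unwrap)) 1 else s$unwrap$per_bp_penalty
    Kg <- model$affinity[[ids[g]]]
    if (is.null(Kg)) Kg <- rep(1, N)
    nmax <- if (cyc) N - 1L else N - m
    if (nmax < 0L) next
    for (n in 0:nmax) {
      for (h1 in 0:hm) for (h2 in 0:(hm - h1)) {
        wgt <- s$activity * Kg[n + 1L] * eps^(h1 + h2)
        if (wgt == 0) next
        pg <- c(pg, g); pn <- c(pn, n); ph1 <- c(ph1, h1); ph2 <- c(ph2, h2)
        pcs <- c(pcs, if (cyc) (n + h1) %% N else n + h1)
        plen <- c(plen, m - h1 - h2)
        pw <- c(pw, wgt)
      }
    }
  }
  ord <- order(pcs)
  pg <- pg[ord]; pn <- pn[ord]; ph1 <- ph1[ord]; ph2 <- ph2[ord]
  pcs <- pcs[ord]; plen <- plen[ord]; pw <- pw[ord]
  P <- length(pg)

  est <- estimate_config_count(N, pcs, plen, cyc)
  if (est > max_configs) {
    abort(sprintf(
      "instance too large to enumerate: about %.3g configurations (cap %.3g)",
      est, max_configs), class = "nucspacing_error")
  }

  # pair weights directly from the rules -------------------------------------
  wmaxL <- max(c(0L, vapply(model$interactions, function(r) length(r$w_values),
                            integer(1))))
  wtab <- array(1, dim = c(G, G, max(wmaxL, 1L)))
  for (r in model$interactions) {
    i1 <- match(r$g1, ids); i2 <- match(r$g2, ids)
    wtab[i1, i2, seq_along(r$w_values)] <- r$w_values
    wtab[i2, i1, seq_along(r$w_values)] <- r$w_values
  }
  w_of <- function(L, g1, g2) if (L < wmaxL) wtab[g1, g2, L + 1L] else 1

  cap <- model$linker_cap
  lam <- if (!is.null(cap)) match(cap$linker, ids) else 0L
  nu <- if (!is.null(cap)) match(cap$nucleosome, ids) else 0L

  cap_legal <- function(gs, cs, ce, wrap_gap = NULL) {
    if (is.null(cap)) return(TRUE)
    n_tok <- length(gs)
    if (n_tok == 0L) return(TRUE)
    cyclic_case <- !is.null(wrap_gap)
    if (cyclic_case && !any(gs == nu)) {
      if (sum(gs == lam) > cap$cap) return(FALSE)
      if (!cap$allow_free_binding && any(gs == lam)) return(FALSE)
      return(TRUE)
    }
    if (cyclic_case) {
      # rotate so the sequence starts at a nucleosome; every linker run is
      # then flanked by nucleosomes on both (cyclic) sides
      first_nu <- which(gs == nu)[1L]
      rot <- c(first_nu:n_tok, seq_len(first_nu - 1L))
      gs_r <- gs[rot]
      runs <- rle(gs_r == lam)
      ends <- cumsum(runs$lengths)
      for (i in seq_along(runs$values)) {
        if (runs$values[i] && runs$lengths[i] > 2L * cap$cap) return(FALSE)
      }
    } else {
      runs <- rle(gs == lam)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (i in seq_along(runs$values)) {
        if (!runs$values[i]) next
        before <- starts[i] > 1L && any(gs[seq_len(starts[i] - 1L)] == nu)
        after <- ends[i] < n_tok && any(gs[(ends[i] + 1L):n_tok] == nu)
        lim <- if (before && after) 2L * cap$cap else cap$cap
        if (runs$lengths[i] > lim) return(FALSE)
      }
    }
    if (!cap$allow_free_binding) {
      gap_left <- function(i) {
        if (i > 1L) cs[i] - ce[i - 1L]
        else if (cyclic_case) wrap_gap else NA_real_
      }
      gap_right <- function(i) {
        if (i < n_tok) cs[i + 1L] - ce[i]
        else if (cyclic_case) wrap_gap else NA_real_
      }
      neigh <- function(i, side) {
        j <- if (side == "L") i - 1L else i + 1L
        if (j >= 1L && j <= n_tok) return(gs[j])
        if (cyclic_case) return(gs[if (side == "L") n_tok else 1L])
        NA_integer_
      }
      for (i in which(gs == lam)) {
        okL <- identical(neigh(i, "L"), nu) &&
          isTRUE(gap_left(i) <= cap$vicinity)
        okR <- identical(neigh(i, "R"), nu) &&
          isTRUE(gap_right(i) <= cap$vicinity)
        if (!okL && !okR) return(FALSE)
      }
    }
    TRUE
  }

  # accumulators --------------------------------------------------------------
  Z <- 0
  cov <- matrix(0, N, G, dimnames = list(NULL, ids))
  stf <- matrix(0, N, G, dimnames = list(NULL, ids))
  freew <- numeric(N)

  covered_of <- function(idx) {
    pos <- integer(0)
    for (q in idx) {
      arc <- pcs[q] + seq_len(plen[q]) - 1L
      pos <- c(pos, if (cyc) arc %% N else arc)
    }
    pos
  }

  tally <- function(idx, wgt) {
    Z <<- Z + wgt
    if (length(idx)) {
      pos <- covered_of(idx)
      for (q in idx) {
        arc <- pcs[q] + seq_len(plen[q]) - 1L
        if (cyc) arc <- arc %% N
        cov[arc + 1L, pg[q]] <<- cov[arc + 1L, pg[q]] + wgt
        stf[pn[q] + 1L, pg[q]] <<- stf[pn[q] + 1L, pg[q]] + wgt
      }
      unc <- setdiff(0:(N - 1L), pos)
    } else {
      unc <- 0:(N - 1L)
    }
    if (length(unc)) freew[unc + 1L] <<- freew[unc + 1L] + wgt
  }

  if (!cyc) {
    recurse <- function(idx, cur_end, wgt) {
      gs <- pg[idx]
      if (cap_legal(gs, pcs[idx], pcs[idx] + plen[idx])) tally(idx, wgt)
      for (q in seq_len(P)) {
        if (pcs[q] < cur_end) next
        if (pcs[q] + plen[q] > N) next
        fac <- pw[q]
        if (length(idx)) {
          last <- idx[length(idx)]
          fac <- fac * w_of(pcs[q] - (pcs[last] + plen[last]), pg[last], pg[q])
        }
        if (fac == 0) next
        recurse(c(idx, q), pcs[q] + plen[q], wgt * fac)
      }
    }
    recurse(integer(0), 0L, 1)
  } else {
    tally(integer(0), 1)   # empty ring
    recurse_ring <- function(idx, cur_end, wgt, cs1, g1) {
      # close the ring at every node
      last <- idx[length(idx)]
      wrap_gap <- cs1 + N - (pcs[last] + plen[last])
      close_fac <- if (length(idx) >= 1L) {
        w_of(wrap_gap, pg[last], g1)
      } else 1
      if (close_fac > 0 &&
          cap_legal(pg[idx], pcs[idx], pcs[idx] + plen[idx], wrap_gap)) {
        tally(idx, wgt * close_fac)
      }
      for (q in seq_len(P)) {
        if (pcs[q] <= cs1) next            # anchor has the smallest start
        if (pcs[q] < cur_end) next
        if (pcs[q] + plen[q] > cs1 + N) next
        fac <- pw[q] * w_of(pcs[q] - (pcs[last] + plen[last]), pg[last], pg[q])
        if (fac == 0) next
        recurse_ring(c(idx, q), pcs[q] + plen[q], wgt * fac, cs1, g1)
      }
    }
    for (q1 in seq_len(P)) {
      recurse_ring(q1, pcs[q1] + plen[q1], pw[q1], pcs[q1], pg[q1])
    }
  }

  structure(
    list(start_prob = stf / Z, coverage = cov / Z, free_prob = freew / Z,
         log_partition = log(Z), N = N, species = ids,
         boundary = model$boundary, method = "enumeration"),
    class = "lattice_solution"
  )
}

# Upper bound on the number of configurations, ignoring interaction weights
# and cap rules (they only remove configurations). For rings the bound is
# the linear count times the number of anchor positions, matching the cost
# of the conditioned enumeration.
estimate_config_count <- function(N, pcs, plen, cyclic) {
  ways <- numeric(N + 1L)
  ways[N + 1L] <- 1
  for (i in N:1) {
    pos <- i - 1L
    ways[i] <- ways[i + 1L]
    qs <- which(pcs == pos)
    for (q in qs) {
      nxt <- pos + plen[q]
      if (nxt <= N) ways[i] <- ways[i] + ways[nxt + 1L]
    }
    if (!is.finite(ways[i]) || ways[i] > 1e15) return(Inf)
  }
  mult <- if (cyclic) N else 1
  min(ways[1L] * mult, Inf)
}
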