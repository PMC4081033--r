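# Internal model compilation: expand species into placement classes,
# build pairwise-weight lookups and the bound-particle state machine used by
# the dynamic-programming solver.
#
# Conventions (internal): positions are 0-based; a particle with nominal
# frame start n and unwrapping (h1, h2) covers [n + h1, n + m - h2). A
# "class" aggregates all (h1, h2) splits with the same total deficit
# u = h1 + h2, because they share the covered length and the per-position
# weight only needs the sum of K over the admissible h1 shifts.

compile_model <- function(model) {
  N <- model$N
  cyc <- model$boundary == "cyclic"
  sp <- model$species
  G <- length(sp)
  ids <- names(sp)

  K <- vector("list", G)
  for (g in seq_len(G)) {
    v <- model$affinity[[ids[g]]]
    if (is.null(v)) v <- rep(1, N)
    m <- sp[[g]]$footprint
    if (!cyc && m > 1L) {
      # frames may not overhang the segment end
      v[seq.int(N - m + 2L, N)] <- 0
    }
    K[[g]] <- v
  }

  # placement classes -------------------------------------------------------
  cls_g <- integer(0); cls_u <- integer(0)
  for (g in seq_len(G)) {
    hm <- if (is.null(sp[[g]]$unwrap)) 0L else sp[[g]]$unwrap$h_max
    cls_g <- c(cls_g, rep.int(g, hm + 1L))
    cls_u <- c(cls_u, 0L:hm)
  }
  C <- length(cls_g)
  cls_len <- integer(C)
  cls_W <- vector("list", C)     # activity * eps^u * sum_h1 K
  cls_Ksum <- vector("list", C)  # sum_h1 K alone (for h1 redistribution)
  for (j in seq_len(C)) {
    g <- cls_g[j]; u <- cls_u[j]
    m <- sp[[g]]$footprint
    cls_len[j] <- m - u
    eps <- if (is.null(sp[[g]]$unwrap)) 1 else sp[[g]]$unwrap$per_bp_penalty
    Ks <- numeric(N)
    for (h1 in 0:u) {
      if (cyc) {
        idx <- ((seq_len(N) - 1L - h1) %% N) + 1L
        Ks <- Ks + K[[g]][idx]
      } else if (h1 < N) {
        # covered start s needs s >= h1; frame-fit is encoded by zeros in K
        Ks[(h1 + 1L):N] <- Ks[(h1 + 1L):N] + K[[g]][1:(N - h1)]
      }
    }
    if (!cyc) {
      # covered stretch must fit: s + len <= N
      len <- cls_len[j]
      if (len > 0L && N - len + 2L <= N) Ks[seq.int(N - len + 2L, N)] <- 0
    }
    cls_Ksum[[j]] <- Ks
    cls_W[[j]] <- sp[[g]]$activity * eps^u * Ks
  }

  rmax <- interaction_range(model$interactions, model$linker_cap)

  # pairwise weights w(L, g1, g2), L = 0..rmax (1 beyond) --------------------
  wpair <- array(1, dim = c(G, G, rmax + 1L))
  for (r in model$interactions) {
    i1 <- match(r$g1, ids); i2 <- match(r$g2, ids)
    L_take <- min(length(r$w_values), rmax + 1L)
    if (L_take > 0L) {
      wpair[i1, i2, seq_len(L_take)] <- r$w_values[seq_len(L_take)]
      wpair[i2, i1, seq_len(L_take)] <- r$w_values[seq_len(L_take)]
    }
  }

  # state machine ------------------------------------------------------------
  cap <- model$linker_cap
  if (is.null(cap)) {
    states <- data.frame(g = seq_len(G))
    sigma <- NULL
  } else {
    lam <- match(cap$linker, ids); nu <- match(cap$nucleosome, ids)
    cc <- cap$cap
    rows <- list()
    for (g in seq_len(G)) {
      if (g == nu) {
        rows[[length(rows) + 1L]] <- c(g, 1L, 0L, 0L, 0L)
      } else if (g == lam) {
        for (B in 0:1) for (k in seq_len(if (B) 2L * cc else cc)) {
          Ps <- if (cap$allow_free_binding) 0L else 0:1
          for (P in Ps) for (D in 0:1) {
            if (D == 1L && B == 0L) next
            rows[[length(rows) + 1L]] <- c(g, B, k, P, D)
          }
        }
      } else {
        for (B in 0:1) for (D in 0:1) {
          if (D == 1L && B == 0L) next
          rows[[length(rows) + 1L]] <- c(g, B, 0L, 0L, D)
        }
      }
    }
    states <- as.data.frame(do.call(rbind, rows))
    names(states) <- c("g", "B", "k", "P", "D")
    sigma <- list(lam = lam, nu = nu, cap = cc, dmax = cap$vicinity,
                  free = cap$allow_free_binding)
  }
  S <- nrow(states)
  state_key <- do.call(paste, c(states, list(sep = "/")))
  find_state <- function(row) match(paste(row, collapse = "/"), state_key)

  # transition: place a particle of species gj at gap L after state st
  # (L = Inf means beyond every interaction/vicinity range).
  # Returns destination state index, or 0 if illegal.
  tau <- function(st, gj, L) {
    if (is.null(sigma)) return(match(gj, states$g))
    B <- states$B[st]; k <- states$k[st]; P <- states$P[st]; D <- states$D[st]
    gprev <- states$g[st]
    if (P == 1L && !(gj == sigma$nu && L <= sigma$dmax)) return(0L)
    if (gj == sigma$nu) return(find_state(c(gj, 1L, 0L, 0L, 0L)))
    if (gj == sigma$lam) {
      k2 <- k + 1L
      if (k2 > (if (B) 2L * sigma$cap else sigma$cap)) return(0L)
      P2 <- if (sigma$free) 0L else {
        if (gprev == sigma$nu && k == 0L && L <= sigma$dmax) 0L else 1L
      }
      return(find_state(c(gj, B, k2, P2, D)))
    }
    find_state(c(gj, B, 0L, 0L, as.integer(D == 1L || k > sigma$cap)))
  }

  # first particle (empty prefix)
  tau0 <- function(gj) {
    if (is.null(sigma)) return(match(gj, states$g))
    if (gj == sigma$nu) return(find_state(c(gj, 1L, 0L, 0L, 0L)))
    if (gj == sigma$lam) {
      P2 <- if (sigma$free) 0L else 1L
      return(find_state(c(gj, 0L, 1L, P2, 0L)))
    }
    find_state(c(gj, 0L, 0L, 0L, 0L))
  }

  end_legal <- if (is.null(sigma)) rep(1, S) else {
    as.numeric(states$P == 0L & states$D == 0L & states$k <= sigma$cap)
  }

  # per (state, class): grouped transition entries ---------------------------
  # entry: dest, w (length rmax+1, legality folded in), plus far destination
  trans <- vector("list", S)
  for (st in seq_len(S)) {
    trans[[st]] <- vector("list", C)
    for (j in seq_len(C)) {
      gj <- cls_g[j]
      dest_by_L <- integer(rmax + 1L)
      w_by_L <- numeric(rmax + 1L)
      for (L in 0:rmax) {
        d <- tau(st, gj, L)
        dest_by_L[L + 1L] <- d
        w_by_L[L + 1L] <- if (d > 0L) wpair[states$g[st], gj, L + 1L] else 0
      }
      far_dest <- tau(st, gj, Inf)
      dests <- unique(dest_by_L[dest_by_L > 0L])
      entries <- lapply(dests, function(d) {
        w <- ifelse(dest_by_L == d, w_by_L, 0)
        list(dest = d, w = w, wrev = rev(w))
      })
      trans[[st]][[j]] <- list(entries = entries, far_dest = far_dest)
    }
  }
  start_dest <- vapply(seq_len(C), function(j) tau0(cls_g[j]), integer(1))

  list(N = N, cyclic = cyc, G = G, ids = ids, footprints =
         vapply(sp, function(s) s$footprint, integer(1)),
       K = K, C = C, cls_g = cls_g, cls_u = cls_u, cls_len = cls_len,
       cls_W = cls_W, cls_Ksum = cls_Ksum,
       rmax = rmax, wpair = wpair, states = states, S = S,
       end_legal = end_legal, trans = trans, start_dest = start_dest,
       has_cap = !is.null(sigma))
}
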