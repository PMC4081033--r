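# Model containers for the 1D lattice description of competitive
# multi-protein binding to DNA.

#' Describe a DNA-binding species
#'
#' A species is a protein (histone octamer, linker histone, transcription
#' factor, ...) that covers `footprint` consecutive base pairs when bound.
#' Its thermodynamic drive is the dimensionless activity `a = K * c0`, the
#' product of the binding constant and the free protein concentration; either
#' supply `activity` directly or supply `binding_constant` (per molar) and
#' `concentration` (molar), which are multiplied internally.
#'
#' A nucleosome-like species may carry an [unwrap_spec()]: the particle keeps
#' its nominal (fully wrapped) frame identity but can peel `h1` and `h2` bp
#' off its two ends, shrinking the covered stretch to
#' `footprint - h1 - h2` while `h1 + h2 <= h_max`.
#'
#' @param id Single string, unique species label (e.g. `"NCP"`, `"H1"`).
#' @param footprint Positive integer, bp covered by the fully wrapped particle.
#' @param activity Dimensionless activity `K * c0` (non-negative). Optional if
#'   `binding_constant` and `concentration` are both given.
#' @param binding_constant,concentration Alternative input form; multiplied to
#'   give the activity.
#' @param unwrap Optional [unwrap_spec()].
#' @param is_nucleosome Logical flag marking the species as the nucleosome core
#'   particle for linker-cap rules and NRL extraction. Defaults to `TRUE` for a
#'   147-bp footprint.
#' @return An object of class `species_spec`.
#' @examples
#' species_spec("NCP", 147, activity = 0.7)
#' species_spec("H1", 15, binding_constant = 2e9, concentration = 1e-10)
#' @export
species_spec <- function(id, footprint, activity = NULL,
                         binding_constant = NULL, concentration = NULL,
                         unwrap = NULL, is_nucleosome = (footprint == 147L)) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop_bad_arg("id", "must be a single non-empty string")
  }
  if (!is_count(footprint, min = 1L)) {
    stop_bad_arg("footprint", "must be a positive integer")
  }
  if (is.null(activity)) {
    if (is.null(binding_constant) || is.null(concentration)) {
      stop_bad_arg("activity",
        "is missing: give it directly or give both `binding_constant` and `concentration`")
    }
    if (!is_number(binding_constant) || binding_constant < 0) {
      stop_bad_arg("binding_constant", "must be a non-negative number")
    }
    if (!is_number(concentration) || concentration < 0) {
      stop_bad_arg("concentration", "must be a non-negative number")
    }
    activity <- binding_constant * concentration
  }
  if (!is_number(activity) || activity < 0) {
    stop_bad_arg("activity", "must be a non-negative number")
  }
  if (!is.null(unwrap)) {
    if (!inherits(unwrap, "unwrap_spec")) {
      stop_bad_arg("unwrap", "must be built with unwrap_spec()")
    }
    if (unwrap$h_max >= footprint) {
      stop_bad_arg("unwrap", "h_max must be smaller than the footprint")
    }
  }
  structure(
    list(id = id, footprint = as.integer(footprint), activity = activity,
         unwrap = unwrap, is_nucleosome = isTRUE(is_nucleosome)),
    class = "species_spec"
  )
}

#' Partial unwrapping rule for a nucleosome-like species
#'
#' Unwrapped states `(h1, h2)` with `h1 + h2 <= h_max` are all enumerated in
#' the ensemble. Each unwrapped base pair contributes a multiplicative
#' Boltzmann factor `per_bp_penalty`; the default 1 is the pure-entropy case
#' in which unwrapping costs no energy and the state count alone drives the
#' thermodynamics.
#'
#' @param h_max Maximum total unwrapping in bp (`0 <= h_max < footprint`).
#' @param per_bp_penalty Statistical weight per unwrapped bp (> 0).
#' @return An object of class `unwrap_spec`.
#' @export
unwrap_spec <- function(h_max, per_bp_penalty = 1) {
  if (!is_count(h_max, min = 0L)) stop_bad_arg("h_max", "must be a non-negative integer")
  if (!is_number(per_bp_penalty) || per_bp_penalty <= 0) {
    stop_bad_arg("per_bp_penalty", "must be a positive number")
  }
  structure(list(h_max = as.integer(h_max), per_bp_penalty = per_bp_penalty),
            class = "unwrap_spec")
}

#' Finite-range interaction between two bound species
#'
#' `w_values[L + 1]` is the multiplicative statistical weight applied when two
#' particles of species `g1` and `g2` are nearest covered neighbours along the
#' DNA with `L` uncovered base pairs between their covered edges
#' (`L = 0` means contact). Beyond the length of `w_values` the weight is 1.
#' The rule is symmetric in `g1`/`g2`.
#'
#' Two classical limits have their own constructors:
#' [contact_cooperativity()] (`w(0) = omega`, all else 1) and
#' [hard_exclusion()] (`w(L) = 0` for `L < V`, else 1).
#'
#' @param g1,g2 Species ids (may be equal).
#' @param w_values Numeric vector of non-negative weights for gaps
#'   `L = 0, 1, ..., length(w_values) - 1`.
#' @return An object of class `interaction_rule`.
#' @export
interaction_rule <- function(g1, g2, w_values) {
  if (!is.character(g1) || length(g1) != 1L) stop_bad_arg("g1", "must be a species id")
  if (!is.character(g2) || length(g2) != 1L) stop_bad_arg("g2", "must be a species id")
  if (!is.numeric(w_values) || length(w_values) < 1L || anyNA(w_values) ||
      any(!is.finite(w_values)) || any(w_values < 0)) {
    stop_bad_arg("w_values", "must be finite non-negative weights")
  }
  structure(list(g1 = g1, g2 = g2, w_values = as.numeric(w_values)),
            class = "interaction_rule")
}

#' @rdname interaction_rule
#' @param omega Contact cooperativity weight `w(0)`.
#' @export
contact_cooperativity <- function(g1, g2, omega) {
  if (!is_number(omega) || omega < 0) stop_bad_arg("omega", "must be non-negative")
  interaction_rule(g1, g2, w_values = omega)
}

#' @rdname interaction_rule
#' @param V Exclusion range in bp: gaps shorter than `V` are prohibited.
#' @export
hard_exclusion <- function(g1, g2, V) {
  if (!is_count(V, min = 1L)) stop_bad_arg("V", "must be a positive integer")
  interaction_rule(g1, g2, w_values = rep(0, V))
}

#' Linker-histone stoichiometry rule
#'
#' Restricts how many linker particles may associate with each nucleosome, in
#' the left-to-right token sequence of bound particles: a maximal run of
#' linker tokens between two nucleosome tokens may hold at most `2 * cap`
#' linkers (one allotment per flanking nucleosome) and at most `cap` before
#' the first or after the last nucleosome. When `allow_free_binding` is
#' `FALSE` every linker must additionally sit within `vicinity` bp of a
#' nucleosome's covered edge (its immediate neighbour in the token sequence),
#' which realizes the "no linker without a nucleosome nearby" limit of strong
#' cooperative linker-nucleosome binding.
#'
#' @param linker,nucleosome Species ids.
#' @param cap Maximum linkers per nucleosome (default 1, the chromatosome
#'   stoichiometry).
#' @param vicinity Maximum uncovered gap in bp between a linker and its
#'   anchoring nucleosome (default 0 = direct contact).
#' @param allow_free_binding If `TRUE`, linkers may also bind DNA away from
#'   any nucleosome (the run caps still apply).
#' @return An object of class `linker_cap_rule`.
#' @export
linker_cap_rule <- function(linker, nucleosome, cap = 1L, vicinity = 0L,
                            allow_free_binding = FALSE) {
  if (!is.character(linker) || length(linker) != 1L) stop_bad_arg("linker", "must be a species id")
  if (!is.character(nucleosome) || length(nucleosome) != 1L) {
    stop_bad_arg("nucleosome", "must be a species id")
  }
  if (identical(linker, nucleosome)) {
    stop_bad_arg("linker", "and `nucleosome` must be different species")
  }
  if (!is_count(cap, min = 1L)) stop_bad_arg("cap", "must be a positive integer")
  if (!is_count(vicinity, min = 0L)) stop_bad_arg("vicinity", "must be a non-negative integer")
  structure(
    list(linker = linker, nucleosome = nucleosome, cap = as.integer(cap),
         vicinity = as.integer(vicinity),
         allow_free_binding = isTRUE(allow_free_binding)),
    class = "linker_cap_rule"
  )
}

#' Assemble a 1D lattice binding model
#'
#' The DNA segment is a lattice of `N` base-pair units, each either covered by
#' one bound particle or free. Particles of the listed species are placed with
#' per-particle statistical weight `a(g) * K(n, g) * eps^(h1 + h2)` (activity,
#' position-specific relative binding constant indexed by the leftmost unit of
#' the nominal fully wrapped frame, and the unwrapping penalty) and pairwise
#' weights `w(L, g1, g2)` between nearest covered neighbours at uncovered gap
#' `L`. Covered stretches never overlap; nominal frames of partially
#' unwrapped neighbours may.
#'
#' Under the default `"hard_wall"` boundary, nominal frames may not overhang
#' the segment ends (affinity values at overhanging start positions are
#' treated as 0). Under `"cyclic"` the lattice is a ring of `N` units;
#' interactions wrap around, which requires every interaction range (and the
#' linker vicinity) to be smaller than `N`.
#'
#' @param N Lattice length in bp.
#' @param species A `species_spec` or list of them; ids must be unique.
#' @param affinity Named list of length-`N` numeric vectors of relative
#'   binding constants `K(n, g)` (name = species id). Species without a track
#'   are homogeneous with `K = 1`. `affinity[[g]][n]` refers to a fully
#'   wrapped frame starting at unit `n` (1-based in R, i.e. frame covers
#'   units `n, ..., n + footprint - 1`).
#' @param interactions List of [interaction_rule()] objects. At most one rule
#'   per unordered species pair.
#' @param linker_cap Optional [linker_cap_rule()].
#' @param boundary `"hard_wall"` or `"cyclic"`.
#' @return An object of class `lattice_model`.
#' @examples
#' m <- lattice_model(1000, species_spec("NCP", 147, activity = 0.5))
#' @export
lattice_model <- function(N, species, affinity = list(), interactions = list(),
                          linker_cap = NULL,
                          boundary = c("hard_wall", "cyclic")) {
  boundary <- match.arg(boundary)
  if (!is_count(N, min = 1L)) stop_bad_arg("N", "must be a positive integer")
  N <- as.integer(N)
  if (inherits(species, "species_spec")) species <- list(species)
  if (!is.list(species) || length(species) == 0L ||
      !all(vapply(species, inherits, logical(1), "species_spec"))) {
    stop_bad_arg("species", "must be a list of species_spec objects")
  }
  ids <- vapply(species, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop_bad_arg("species", "ids must be unique")
  names(species) <- ids
  fps <- vapply(species, function(s) s$footprint, integer(1))
  if (N < max(fps)) {
    abort(sprintf("lattice (N = %d) is shorter than the largest footprint (%d)",
                  N, max(fps)), class = "nucspacing_error")
  }

  if (length(affinity)) {
    if (is.null(names(affinity)) || !all(names(affinity) %in% ids)) {
      stop_bad_arg("affinity", "must be named by species id")
    }
    for (nm in names(affinity)) {
      v <- affinity[[nm]]
      if (!is.numeric(v) || length(v) != N) {
        stop_bad_arg("affinity", sprintf("track for '%s' must be numeric of length N", nm))
      }
      if (anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
        stop_bad_arg("affinity", sprintf("track for '%s' must be finite and non-negative", nm))
      }
      affinity[[nm]] <- as.numeric(v)
    }
  }

  if (inherits(interactions, "interaction_rule")) interactions <- list(interactions)
  if (!all(vapply(interactions, inherits, logical(1), "interaction_rule"))) {
    stop_bad_arg("interactions", "must be a list of interaction_rule objects")
  }
  pair_key <- character(0)
  for (r in interactions) {
    if (!all(c(r$g1, r$g2) %in% ids)) {
      abort(sprintf("interaction rule refers to unknown species '%s'/'%s'", r$g1, r$g2),
            class = "nucspacing_error")
    }
    key <- paste(sort(c(r$g1, r$g2)), collapse = "\r")
    if (key %in% pair_key) {
      abort(sprintf("multiple interaction rules for pair (%s, %s)", r$g1, r$g2),
            class = "nucspacing_error")
    }
    pair_key <- c(pair_key, key)
  }

  if (!is.null(linker_cap)) {
    if (!inherits(linker_cap, "linker_cap_rule")) {
      stop_bad_arg("linker_cap", "must be built with linker_cap_rule()")
    }
    if (!all(c(linker_cap$linker, linker_cap$nucleosome) %in% ids)) {
      stop_bad_arg("linker_cap", "refers to species absent from the model")
    }
  }

  rmax <- interaction_range(interactions, linker_cap)
  if (boundary == "cyclic" && rmax >= N) {
    abort(sprintf(
      "interaction range (%d) must be smaller than N (%d) under a cyclic boundary",
      rmax, N), class = "nucspacing_error")
  }

  structure(
    list(N = N, species = species, affinity = affinity,
         interactions = interactions, linker_cap = linker_cap,
         boundary = boundary),
    class = "lattice_model"
  )
}

# Largest gap L at which any pairwise weight can differ from 1 (the linker
# vicinity counts because anchoring legality depends on the gap).
interaction_range <- function(interactions, linker_cap) {
  r <- 0L
  for (rule in interactions) {
    w <- rule$w_values
    keep <- which(w != 1)
    if (length(keep)) r <- max(r, max(keep) - 1L)
  }
  if (!is.null(linker_cap)) r <- max(r, linker_cap$vicinity)
  as.integer(r)
}

#' @export
print.species_spec <- function(x, ...) {
  un <- if (is.null(x$unwrap)) "none" else {
    sprintf("h_max = %d, per-bp penalty = %g", x$unwrap$h_max, x$unwrap$per_bp_penalty)
  }
  cat(sprintf("<species_spec> %s: footprint %d bp, activity %g, unwrapping %s%s\n",
              x$id, x$footprint, x$activity, un,
              if (x$is_nucleosome) " [nucleosome]" else ""))
  invisible(x)
}

#' @export
print.lattice_model <- function(x, ...) {
  cat(sprintf("<lattice_model> N = %d bp, boundary = %s\n", x$N, x$boundary))
  for (s in x$species) {
    trk <- if (s$id %in% names(x$affinity)) "sequence-specific" else "homogeneous"
    cat(sprintf("  %s (m = %d, a = %g, %s)\n", s$id, s$footprint, s$activity, trk))
  }
  if (length(x$interactions)) {
    for (r in x$interactions) {
      cat(sprintf("  w(%s, %s): range %d\n", r$g1, r$g2, length(r$w_values) - 1L))
    }
  }
  if (!is.null(x$linker_cap)) {
    cat(sprintf("  linker cap: <= %d %s per %s (vicinity %d bp, free binding %s)\n",
                x$linker_cap$cap, x$linker_cap$linker, x$linker_cap$nucleosome,
                x$linker_cap$vicinity,
                if (x$linker_cap$allow_free_binding) "allowed" else "forbidden"))
  }
  invisible(x)
}
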