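# Seeded generators for every input class the analyses consume, plus the
# packaged satellite repeat unit. All generators are pure functions of
# their arguments and seed.

#' The 234-bp mouse major satellite consensus repeat unit
#'
#' The conserved repeat unit of mouse pericentric heterochromatin used as
#' the tandem-repeat reference for the satellite analyses.
#'
#' @return A single 234-character DNA string.
#' @examples
#' nchar(satellite_unit())
#' @export
satellite_unit <- function() {
  paste0(
    "GGACCTGGAATATGGCGAGAAAACTGAAAATCACGGAAAATGAGAAATACACACTTTA",
    "GGACGTGAAATATGGCGAGGAAAACTGAAAAAGGTGGAAAATTTAGAAATGTCCACTGTA",
    "GGACGTGGAATATGGCAAGAAAACTGAAAATCATGGAAAATGAGAAACATCCACT",
    "TGACGACTTGAAAAATGACGAAATCACTAAAAAACGTGAAAAATGAGAAATGCACACTGAA"
  )
}

#' Homogeneous boundary model at a target density
#'
#' Builds a hard-wall lattice model of a single nucleosome-like species
#' whose interior covered fraction matches `density_target`; the activity is
#' found by inverting the McGhee-von Hippel isotherm, so the statistical
#' positioning oscillations near the wall sit on a controlled bulk density.
#'
#' @param density_target Target interior covered fraction in (0, 1).
#' @param N Lattice length in bp (default 4000).
#' @param footprint Species footprint (default 147).
#' @param unwrap Optional [unwrap_spec()] attached to the species.
#' @param interactions,linker_cap Forwarded to [lattice_model()].
#' @param extra_species Optional list of additional [species_spec()]s.
#' @return A [lattice_model()].
#' @export
gen_boundary_model <- function(density_target, N = 4000, footprint = 147,
                               unwrap = NULL, interactions = list(),
                               linker_cap = NULL, extra_species = list()) {
  if (!is_number(density_target) || density_target <= 0 || density_target >= 1) {
    stop_bad_arg("density_target", "must be in (0, 1)")
  }
  a <- mcghee_von_hippel_activity(footprint, density_target)
  sp <- c(list(species_spec("NCP", footprint, activity = a, unwrap = unwrap,
                            is_nucleosome = TRUE)),
          extra_species)
  lattice_model(N, sp, interactions = interactions, linker_cap = linker_cap)
}

#' Seeded synthetic fragment sets on the padded satellite reference
#'
#' Samples paired-end-style fragments whose left ends are drawn from a
#' mixture of Gaussian modes on the repeat unit and whose lengths are drawn
#' from a truncated Gaussian, emulating size-selected MNase fragments with
#' phased start sites.
#'
#' @param n Number of fragments.
#' @param modes Data frame (or list coercible to one) with columns
#'   `position`, `sd`, `weight`; weights must sum to 1.
#' @param length_dist Numeric `c(mean, sd, min, max)` for fragment lengths
#'   (default `c(147, 2, 140, 155)`).
#' @param seed Integer seed; the generator is deterministic per seed.
#' @param unit_length,pad Reference geometry (default 234 + 49).
#' @return A wrapped fragment tibble as from [wrap_fragments()].
#' @export
gen_fragment_set <- function(n, modes, length_dist = c(147, 2, 140, 155),
                             seed = 1L, unit_length = 234, pad = 49) {
  if (!is_count(n)) stop_bad_arg("n", "must be a positive integer")
  modes <- as_tibble(modes)
  if (!all(c("position", "sd", "weight") %in% names(modes))) {
    stop_bad_arg("modes", "needs columns position, sd, weight")
  }
  if (abs(sum(modes$weight) - 1) > 1e-9) {
    stop_bad_arg("modes", "weights must sum to 1")
  }
  if (length(length_dist) != 4L) {
    stop_bad_arg("length_dist", "must be c(mean, sd, min, max)")
  }
  with_local_seed(seed, {
    comp <- sample.int(nrow(modes), n, replace = TRUE, prob = modes$weight)
    left <- round(stats::rnorm(n, modes$position[comp], modes$sd[comp]))
    left <- ((left %% unit_length) + unit_length) %% unit_length
    len <- round(stats::rnorm(n, length_dist[1], length_dist[2]))
    len <- pmin(pmax(len, length_dist[3]), length_dist[4])
    out <- tibble(left = as.integer(left),
                  right = as.integer(left + len),
                  length = as.integer(len))
    attr(out, "unit_length") <- as.integer(unit_length)
    attr(out, "pad") <- as.integer(pad)
    out
  })
}

#' Seeded synthetic anchor-centred occupancy track
#'
#' Builds a single-chromosome occupancy track that carries a damped cosine
#' of the requested period around each anchor (with per-anchor positional
#' jitter), on a baseline of 1 — the structure of phased nucleosome arrays
#' around regulatory anchors.
#'
#' @param track_length Track length in bp.
#' @param anchors Integer anchor positions (1-based).
#' @param period Oscillation period in bp.
#' @param amplitude Cosine amplitude relative to baseline 1.
#' @param jitter_sd Per-anchor positional jitter (bp, Gaussian, rounded).
#' @param span Half-width over which the oscillation is laid down.
#' @param seed Integer seed.
#' @return List with `track` (numeric vector) and `anchors` (tibble
#'   chrom/position/strand).
#' @export
gen_phased_track <- function(track_length, anchors, period = 200,
                             amplitude = 0.3, jitter_sd = 5, span = 1600,
                             seed = 1L) {
  with_local_seed(seed, {
    tr <- rep(1, track_length)
    jit <- round(stats::rnorm(length(anchors), 0, jitter_sd))
    for (i in seq_along(anchors)) {
      ctr <- anchors[i] + jit[i]
      lo <- max(1L, ctr - span); hi <- min(track_length, ctr + span)
      x <- lo:hi
      tr[x] <- tr[x] + amplitude * cos(2 * pi * (x - ctr) / period)
    }
    list(track = tr,
         anchors = tibble(chrom = "*", position = as.integer(anchors),
                          strand = "+"))
  })
}
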