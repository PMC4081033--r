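# Ready-made study conditions: the tandem satellite array and the
# linker-histone titration used for the headline NRL results.

#' Sequence-driven nucleosome model of a tandem satellite array
#'
#' Tiles the repeat unit head-to-tail with cyclic padding, derives a
#' sequence affinity track from the tiled sequence with
#' [gc_window_affinity()] (any per-unit-periodic preference model serves the
#' same purpose), and assembles a single-nucleosome lattice model in the
#' sequence-dominant regime: the activity is kept low so that particle
#' positions follow the per-unit affinity maxima rather than packing
#' pressure.
#'
#' @param unit Repeat unit (default [satellite_unit()]).
#' @param copies Tandem copies (default 50).
#' @param pad Cyclic padding in nt (default 49).
#' @param activity Nucleosome activity (default 0.05, sequence-dominant).
#' @param beta Inverse energy scale of the GC surrogate (default 10).
#' @param footprint Nucleosome footprint (default 147).
#' @return A [lattice_model()] whose `N` is `copies * nchar(unit) + pad`.
#' @export
satellite_array_model <- function(unit = satellite_unit(), copies = 50,
                                  pad = 49, activity = 0.05, beta = 10,
                                  footprint = 147) {
  seqs <- tile_repeat(unit, copies, pad)
  K <- gc_window_affinity(seqs, width = footprint, beta = beta,
                          smooth = footprint)
  lattice_model(nchar(seqs), species_spec("NCP", footprint, activity = activity),
                affinity = list(NCP = K))
}

#' NRL of the satellite array in the sequence-dominant regime
#'
#' Solves the [satellite_array_model()] and fits the NRL over a window
#' spanning many repeat units. With a per-unit-periodic affinity landscape
#' the fitted NRL equals the repeat unit length.
#'
#' @inheritParams satellite_array_model
#' @param trim_units Repeat units excluded at each array end so that the
#'   hard-wall boundary does not distort the fitted spacing (default 2).
#' @return An `nrl_estimate`.
#' @export
satellite_nrl <- function(unit = satellite_unit(), copies = 50, pad = 49,
                          activity = 0.05, beta = 10, trim_units = 2) {
  model <- satellite_array_model(unit, copies, pad, activity, beta)
  sol <- lattice_solve(model)
  U <- nchar(unit)
  lo <- trim_units * U + 1L
  hi <- model$N - trim_units * U - pad
  fit_nrl(find_occupancy_peaks(sol$coverage[lo:hi, 1L]))
}

#' Linker-histone titration of the NRL
#'
#' The two-species homogeneous model behind the linker-histone results: a
#' nucleosome species at fixed activity plus a linker species whose
#' activity is scanned, bound by the chromatosome stoichiometry rule
#' ([linker_cap_rule()]: at most `cap` linkers per nucleosome, each within
#' `vicinity` bp of a nucleosome edge, no free binding). The NRL is fitted
#' from the boundary-induced occupancy oscillations at every activity, and
#' the bound linker-per-nucleosome ratio is reported alongside.
#'
#' @param linker_activities Numeric vector of linker activities `K * c0` to
#'   scan.
#' @param ncp_activity Nucleosome activity (default 0.7).
#' @param linker_footprint Linker footprint in bp (default 15).
#' @param cap,vicinity,allow_free_binding Stoichiometry rule (defaults: one
#'   linker per nucleosome within 5 bp of its edge, no free binding; the
#'   nonzero vicinity keeps linker-nucleosome distances flexible).
#' @param N Lattice length (default 4000).
#' @param window Analysis window for the NRL fit (default 1500).
#' @return Tibble with columns `linker_activity`, `nrl`, `stderr`,
#'   `r_squared`, `n_peaks`, `bound_ratio`, `ok`.
#' @export
linker_titration_scan <- function(linker_activities, ncp_activity = 0.7,
                                  linker_footprint = 15, cap = 1,
                                  vicinity = 5, allow_free_binding = FALSE,
                                  N = 4000, window = 1500) {
  rows <- purrr::map(linker_activities, function(al) {
    model <- lattice_model(
      N,
      list(species_spec("NCP", 147, activity = ncp_activity),
           species_spec("H1", linker_footprint, activity = al,
                        is_nucleosome = FALSE)),
      linker_cap = if (al > 0) {
        linker_cap_rule("H1", "NCP", cap = cap, vicinity = vicinity,
                        allow_free_binding = allow_free_binding)
      }
    )
    sol <- lattice_solve(model)
    ratio <- sum(sol$start_prob[, "H1"]) / sum(sol$start_prob[, "NCP"])
    est <- tryCatch(
      fit_nrl(find_occupancy_peaks(sol$coverage[seq_len(window), "NCP"])),
      nucspacing_insufficient_peaks = function(e) NULL)
    if (is.null(est)) {
      tibble(linker_activity = al, nrl = NA_real_, stderr = NA_real_,
             r_squared = NA_real_, n_peaks = NA_integer_,
             bound_ratio = ratio, ok = FALSE)
    } else {
      tibble(linker_activity = al, nrl = est$nrl, stderr = est$stderr,
             r_squared = est$r_squared, n_peaks = est$n_peaks,
             bound_ratio = ratio, ok = TRUE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Default linker-titration grid
#'
#' Doubling grid spanning the rise and saturation of the NRL-versus-linker
#' curve under the default titration conditions.
#'
#' @return Numeric vector of linker activities.
#' @export
linker_titration_grid <- function() {
  c(0, 0.0125, 0.025, 0.05, 0.075, 0.1, 0.15, 0.2, 0.3, 0.4, 0.6, 0.8,
    1.2, 1.6, 2.4, 3.2, 4.8, 6.4)
}

#' Steepest doubling response of an NRL titration
#'
#' Scans all pairs `(a, 2a)` present in the titration grid and returns the
#' largest NRL difference — the strongest experimentally detectable NRL
#' change obtainable by doubling the linker-to-core ratio.
#'
#' @param scan Tibble from [linker_titration_scan()].
#' @param tol Relative tolerance for matching `2a` in the grid.
#' @return One-row tibble: `activity_low`, `activity_high`, `nrl_low`,
#'   `nrl_high`, `delta_nrl`.
#' @export
steepest_doubling <- function(scan, tol = 1e-8) {
  ok <- scan[scan$ok & scan$linker_activity > 0, ]
  best <- NULL
  for (i in seq_len(nrow(ok))) {
    a <- ok$linker_activity[i]
    j <- which(abs(ok$linker_activity - 2 * a) <= tol * 2 * a)
    if (!length(j)) next
    d <- ok$nrl[j[1]] - ok$nrl[i]
    if (is.null(best) || d > best$delta_nrl) {
      best <- tibble(activity_low = a, activity_high = 2 * a,
                     nrl_low = ok$nrl[i], nrl_high = ok$nrl[j[1]],
                     delta_nrl = d)
    }
  }
  if (is.null(best)) abort("no doubling pair found in the scan grid",
                           class = "nucspacing_error")
  best
}
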