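# NRL extraction: peak detection on an occupancy profile followed by linear
# regression of peak position against peak index. The slope is the
# nucleosome repeat length.

#' Find peaks in a per-bp occupancy profile
#'
#' Local maxima are filtered by topographic prominence (the drop from the
#' peak to the highest saddle separating it from higher ground) and by a
#' minimum mutual separation, keeping the more prominent peak of any close
#' pair. The profile is assumed to start at the boundary of interest, so
#' peak order equals distance from the boundary.
#'
#' @param profile Numeric vector of per-bp occupancy, or a data frame with an
#'   `occupancy` column. Position 1 is the boundary.
#' @param min_prominence Minimum prominence as a fraction of the profile
#'   range (default 0.02).
#' @param min_separation Minimum distance between reported peaks in bp
#'   (default 100, below any plausible NRL but above noise wiggles).
#' @return A `peak_set` tibble with columns `index` (0-based, boundary
#'   outward), `position` (bp from the profile start, 1-based), `height`, and
#'   `prominence`. A flat profile yields zero rows.
#' @export
find_occupancy_peaks <- function(profile, min_prominence = 0.02,
                                 min_separation = 100) {
  y <- as_profile(profile, col = "occupancy")
  n <- length(y)
  if (n < 3L * min_separation) {
    stop_bad_arg("profile", "is too short for the requested min_separation")
  }
  rng <- diff(range(y))
  empty <- tibble(index = integer(), position = integer(),
                  height = numeric(), prominence = numeric())
  class(empty) <- c("peak_set", class(empty))
  if (rng == 0) return(empty)

  # candidate local maxima; plateaus contribute their centre
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j <= n - 1L && y[j + 1L] < y[j]) {
        cand <- c(cand, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(empty)

  prom <- vapply(cand, function(p) {
    h <- y[p]
    lmin <- h; k <- p
    while (k > 1L) { k <- k - 1L; if (y[k] > h) break; lmin <- min(lmin, y[k]) }
    lbase <- if (y[k] > h) lmin else min(lmin, y[seq_len(p)])
    rmin <- h; k <- p
    while (k < n) { k <- k + 1L; if (y[k] > h) break; rmin <- min(rmin, y[k]) }
    rbase <- if (y[k] > h) rmin else min(rmin, y[p:n])
    h - max(lbase, rbase)
  }, numeric(1))

  keep <- prom >= min_prominence * rng
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)

  # enforce separation, keeping the more prominent of close pairs
  ord <- order(-prom, cand)
  sel <- logical(length(cand))
  taken <- integer(0)
  for (k in ord) {
    if (!length(taken) || all(abs(cand[k] - taken) >= min_separation)) {
      sel[k] <- TRUE
      taken <- c(taken, cand[k])
    }
  }
  pos <- sort(cand[sel])
  out <- tibble(index = seq_along(pos) - 1L, position = pos,
                height = y[pos], prominence = prom[sel][order(cand[sel])])
  class(out) <- c("peak_set", class(out))
  out
}

#' Estimate the nucleosome repeat length from peak positions
#'
#' Ordinary least-squares regression of peak position on peak index
#' (0, 1, 2, ... from the boundary outward). The slope is the NRL in bp per
#' nucleosome; its standard error and the fit R-squared quantify how regular
#' the array is.
#'
#' @param peaks A `peak_set` from [find_occupancy_peaks()], or a numeric
#'   vector of peak positions ordered from the boundary.
#' @return An `nrl_estimate` with fields `nrl`, `intercept`, `r_squared`,
#'   `stderr`, `n_peaks`.
#' @examples
#' fit_nrl(c(100, 300, 500))   # exact 200-bp ladder
#' @export
fit_nrl <- function(peaks) {
  pos <- if (is.data.frame(peaks)) peaks$position else as.numeric(peaks)
  if (is.unsorted(pos, strictly = TRUE)) {
    stop_bad_arg("peaks", "positions must be strictly increasing")
  }
  if (length(pos) < 3L) {
    abort(sprintf("need at least 3 peaks to fit an NRL (got %d)", length(pos)),
          class = "nucspacing_insufficient_peaks")
  }
  idx <- seq_along(pos) - 1
  fit <- lm(pos ~ idx)
  # exactly periodic peaks give a perfect fit; that is a valid outcome here
  sm <- suppressWarnings(summary(fit))
  structure(
    list(nrl = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         r_squared = sm$r.squared, stderr = sm$coefficients[2L, 2L],
         n_peaks = length(pos), peaks = pos),
    class = "nrl_estimate"
  )
}

#' @export
print.nrl_estimate <- function(x, ...) {
  cat(sprintf("<nrl_estimate> NRL = %.2f bp (se %.3g, r^2 %.5f, %d peaks)\n",
              x$nrl, x$stderr, x$r_squared, x$n_peaks))
  invisible(x)
}

#' @describeIn fit_nrl One-row tibble of the estimate.
#' @param x An `nrl_estimate`.
#' @param ... Unused.
#' @export
tidy.nrl_estimate <- function(x, ...) {
  tibble(nrl = x$nrl, intercept = x$intercept, stderr = x$stderr,
         r_squared = x$r_squared, n_peaks = x$n_peaks)
}

#' @describeIn fit_nrl Alias of `tidy()` for the one-row summary.
#' @export
glance.nrl_estimate <- function(x, ...) tidy(x)

#' NRL of a solved lattice model
#'
#' Convenience pipeline: solve the model (if needed), take the coverage of
#' the nucleosome species near the chosen boundary, detect occupancy peaks
#' within the analysis window and regress position on index.
#'
#' @param x A `lattice_model` or `lattice_solution`.
#' @param species Species id to profile; defaults to the species flagged
#'   `is_nucleosome` (or the first species).
#' @param window Analysis window in bp from the boundary (default 1500).
#' @param from `"left"` or `"right"` segment end to use as the boundary; the
#'   profile is oriented boundary-outward either way.
#' @param min_prominence,min_separation Passed to [find_occupancy_peaks()].
#' @return An `nrl_estimate`.
#' @export
occupancy_nrl <- function(x, species = NULL, window = 1500,
                          from = c("left", "right"),
                          min_prominence = 0.02, min_separation = 100) {
  from <- match.arg(from)
  sol <- if (inherits(x, "lattice_model")) lattice_solve(x) else x
  stopifnot(inherits(sol, "lattice_solution"))
  if (is.null(species)) {
    species <- if (inherits(x, "lattice_model")) {
      flags <- vapply(x$species, function(s) s$is_nucleosome, logical(1))
      if (any(flags)) names(x$species)[which(flags)[1L]] else sol$species[1L]
    } else sol$species[1L]
  }
  prof <- sol$coverage[, species]
  if (from == "right") prof <- rev(prof)
  prof <- prof[seq_len(min(length(prof), window))]
  fit_nrl(find_occupancy_peaks(prof, min_prominence, min_separation))
}

#' Scan a model parameter and track the NRL
#'
#' Builds one model per grid value with `model_factory`, solves it and fits
#' the NRL from the boundary-induced occupancy oscillations. Grid points with
#' fewer than 3 detectable peaks are flagged rather than aborting the scan.
#'
#' @param model_factory Function taking one grid value and returning a
#'   [lattice_model()].
#' @param grid Numeric vector of parameter values.
#' @param ... Passed to [occupancy_nrl()] (window, species, peak options).
#' @return A tibble with columns `parameter`, `nrl`, `stderr`, `r_squared`,
#'   `n_peaks`, `ok`.
#' @examples
#' \donttest{
#' scan_nrl(function(v) {
#'   lattice_model(3000, species_spec("NCP", 147, activity = 0.5),
#'                 interactions = list(hard_exclusion("NCP", "NCP", v)))
#' }, grid = c(10, 20, 30))
#' }
#' @export
scan_nrl <- function(model_factory, grid, ...) {
  rows <- purrr::map(grid, function(v) {
    model <- model_factory(v)
    est <- tryCatch(occupancy_nrl(model, ...),
                    nucspacing_insufficient_peaks = function(e) NULL)
    if (is.null(est)) {
      tibble(parameter = v, nrl = NA_real_, stderr = NA_real_,
             r_squared = NA_real_, n_peaks = NA_integer_, ok = FALSE)
    } else {
      tibble(parameter = v, nrl = est$nrl, stderr = est$stderr,
             r_squared = est$r_squared, n_peaks = est$n_peaks, ok = TRUE)
    }
  })
  dplyr::bind_rows(rows)
}
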