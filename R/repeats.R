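# Cyclic-coordinate fragment analyses on tandem repeats: end-frequency
# profiles, size selection, and start-site periodicity.

#' Wrap fragment coordinates into canonical cyclic repeat coordinates
#'
#' Fragments mapped to a padded tandem-repeat reference (unit length `U`
#' plus `pad` leading nucleotides appended at the right end) are reduced so
#' that each left end lies in `[0, U)`; right ends move with their fragment
#' (and may exceed `U`), so fragment lengths are untouched. Intervals are
#' half-open `[left, right)`, 0-based.
#'
#' @param fragments Data frame with columns `left` and `right` (0-based,
#'   half-open) on the padded reference.
#' @param unit_length Repeat unit length U in bp (default 234, the mouse
#'   major satellite unit).
#' @param pad Padding length in bp (default 49).
#' @return A tibble with columns `left`, `right`, `length`, left ends in
#'   `[0, U)`; carries attributes `unit_length` and `pad`.
#' @export
wrap_fragments <- function(fragments, unit_length = 234, pad = 49) {
  fr <- validate_fragments(fragments, unit_length, pad)
  shift <- (fr$left %/% unit_length) * unit_length
  out <- tibble(left = fr$left - shift, right = fr$right - shift,
                length = fr$right - fr$left)
  attr(out, "unit_length") <- as.integer(unit_length)
  attr(out, "pad") <- as.integer(pad)
  out
}

validate_fragments <- function(fragments, unit_length, pad) {
  if (!is.data.frame(fragments) || !all(c("left", "right") %in% names(fragments))) {
    stop_bad_arg("fragments", "must have columns left and right")
  }
  if (!is_count(unit_length)) stop_bad_arg("unit_length", "must be a positive integer")
  if (!is_count(pad, min = 0L)) stop_bad_arg("pad", "must be a non-negative integer")
  left <- as.integer(fragments$left); right <- as.integer(fragments$right)
  if (any(right <= left)) stop_bad_arg("fragments", "must satisfy right > left")
  if (any(left < 0)) stop_bad_arg("fragments", "must have non-negative left ends")
  if (any(right - left > unit_length + pad)) {
    abort("fragment longer than the padded reference unit", class = "nucspacing_error")
  }
  list(left = left, right = right)
}

#' Per-position frequencies of fragment left and right ends
#'
#' Counts, for every position of the repeat unit `[0, U)`, how many
#' fragments start (left end) and how many end (right end, reduced modulo
#' `U`) there; each fragment contributes one left and one right count.
#' An optional inclusive length range restricts the fragments first (the
#' mono-nucleosome size selection).
#'
#' @param fragments Wrapped fragments from [wrap_fragments()] (or any data
#'   frame with `left`, `right` in cyclic coordinates).
#' @param length_range Optional inclusive `c(min, max)` fragment-length
#'   filter in bp.
#' @param unit_length Repeat unit length; taken from the `fragments`
#'   attribute when present.
#' @return A tibble with columns `position` (0-based, `0..U-1`),
#'   `left_count`, `right_count`.
#' @export
end_frequency_profile <- function(fragments, length_range = NULL,
                                  unit_length = NULL) {
  U <- unit_length %||% attr(fragments, "unit_length") %||% 234L
  if (!all(c("left", "right") %in% names(fragments))) {
    stop_bad_arg("fragments", "must have columns left and right")
  }
  len <- fragments$right - fragments$left
  if (!is.null(length_range)) {
    if (length(length_range) != 2L || length_range[1] > length_range[2]) {
      stop_bad_arg("length_range", "must be c(min, max) with min <= max")
    }
    keep <- len >= length_range[1] & len <= length_range[2]
    fragments <- fragments[keep, , drop = FALSE]
  }
  pos <- 0:(U - 1L)
  lc <- tabulate(fragments$left %% U + 1L, nbins = U)
  rc <- tabulate(fragments$right %% U + 1L, nbins = U)
  tibble(position = pos, left_count = lc, right_count = rc)
}

#' Dominant periodicity of start-site counts by autocorrelation
#'
#' Circular autocorrelation of the mean-subtracted per-position counts; the
#' dominant period is read from the lags of maximal autocorrelation within
#' `lag_range` (default `[3, U/2]`, excluding the trivial lag 0). Because a
#' phased comb autocorrelates equally at every multiple of its fundamental,
#' ties and noise-perturbed ties among multiples are resolved toward the
#' smallest near-maximal lag. Suited to the 10-bp rotational phasing of nucleosome start sites on
#' satellite repeats, but makes no assumption about the value of the
#' period.
#'
#' @param counts Numeric vector of per-position start-site counts over a
#'   cyclic domain (e.g. `left_count` from [end_frequency_profile()]), or
#'   that tibble itself.
#' @param lag_range Integer bounds for the candidate period in bp; default
#'   `c(3, floor(length(counts) / 2))`.
#' @return A `periodicity_result` with `period`, the full `autocorrelation`
#'   tibble (lag, value), and the mean-subtracted counts as `detrended`.
#' @export
autocorr_period <- function(counts, lag_range = NULL) {
  if (is.data.frame(counts)) counts <- counts$left_count %||% counts[[2]]
  y <- as.numeric(counts)
  U <- length(y)
  if (U < 6L) stop_bad_arg("counts", "domain is too short")
  if (all(y == 0)) {
    warn("all counts are zero; no period detected")
    out <- list(period = NA_real_,
                autocorrelation = tibble(lag = integer(), value = numeric()),
                detrended = y - mean(y))
    return(structure(out, class = "periodicity_result"))
  }
  z <- y - mean(y)
  # circular autocorrelation via FFT
  ac <- Re(fft(Mod(fft(z))^2, inverse = TRUE)) / U
  ac <- ac / ac[1L]
  lags <- 1:(U - 1L)
  lr <- lag_range %||% c(3L, floor(U / 2))
  cand <- lags[lags >= lr[1] & lags <= lr[2]]
  if (!length(cand)) stop_bad_arg("lag_range", "contains no usable lag")
  # a comb is periodic at every multiple of its fundamental, so noise can
  # hand the raw maximum to any multiple; collect the near-maximal lags and
  # return the smallest one whose multiples are themselves near-maximal
  vals <- ac[cand + 1L]
  mx <- max(vals)
  delta <- 0.25 * (mx - stats::median(vals))
  best <- min(cand[vals >= mx - delta])
  structure(
    list(period = as.numeric(best),
         autocorrelation = tibble(lag = lags, value = ac[lags + 1L]),
         detrended = z),
    class = "periodicity_result"
  )
}
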