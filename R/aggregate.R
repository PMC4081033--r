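# Anchor-centred extraction, normalization, averaging and sorting of
# per-bp occupancy tracks.

#' Extract and average anchor-centred occupancy windows
#'
#' For every anchor, the per-bp occupancy over `window` around the anchor
#' position is extracted, oriented (minus-strand windows are reversed when
#' `flip_minus_strand` is on), and normalized so the leftmost (most upstream)
#' value of the window equals 1; the aggregate profile is the column mean of
#' the normalized rows. Anchors whose window leaves the track, and rows
#' whose leftmost value is 0 (normalization undefined), are dropped and
#' counted.
#'
#' @param track Named list of per-bp numeric vectors (one per chromosome,
#'   1-based positions), as returned by [read_occupancy_bedgraph()], or a
#'   single numeric vector (treated as one unnamed chromosome).
#' @param anchors Data frame with columns `chrom`, `position` (1-based
#'   summit) and optionally `strand` (`"+"`/`"-"`), e.g. from
#'   [read_bed_anchors()]. A numeric vector is accepted when the track is a
#'   single vector.
#' @param window Length-2 integer vector of window bounds in bp relative to
#'   the anchor (default `c(-1500, 1500)`).
#' @param flip_minus_strand Reverse windows of minus-strand anchors so that
#'   all rows read boundary-outward in the same orientation (default `TRUE`).
#' @param normalize Normalize each row to 1 at its leftmost position
#'   (default `TRUE`).
#' @return A `profile_matrix`: list with `matrix` (anchors x offsets,
#'   offsets as column names), `average` (tibble offset/occupancy),
#'   `n_used`, `n_dropped_window`, `n_dropped_zero`.
#' @export
extract_profile_matrix <- function(track, anchors, window = c(-1500, 1500),
                                   flip_minus_strand = TRUE, normalize = TRUE) {
  if (is.numeric(track)) track <- list(`*` = track)
  if (!is.list(track) || !all(vapply(track, is.numeric, logical(1)))) {
    stop_bad_arg("track", "must be a numeric vector or named list of numeric vectors")
  }
  if (is.numeric(anchors)) {
    anchors <- tibble(chrom = names(track)[1], position = anchors)
  }
  if (!is.data.frame(anchors) || !all(c("chrom", "position") %in% names(anchors))) {
    stop_bad_arg("anchors", "must have columns chrom and position")
  }
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_bad_arg("window", "must be increasing bounds c(lower, upper)")
  }
  offs <- window[1]:window[2]
  strand <- if ("strand" %in% names(anchors)) anchors$strand else rep("+", nrow(anchors))

  rows <- list()
  n_drop_win <- 0L
  n_drop_zero <- 0L
  miss_warned <- FALSE
  for (i in seq_len(nrow(anchors))) {
    tr <- track[[anchors$chrom[i]]]
    if (is.null(tr)) { n_drop_win <- n_drop_win + 1L; next }
    idx <- anchors$position[i] + offs
    if (idx[1] < 1L || idx[length(idx)] > length(tr)) {
      n_drop_win <- n_drop_win + 1L
      next
    }
    v <- tr[idx]
    if (anyNA(v)) {
      if (!miss_warned) {
        warn("missing track values inside windows treated as 0 coverage")
        miss_warned <- TRUE
      }
      v[is.na(v)] <- 0
    }
    if (flip_minus_strand && identical(strand[i], "-")) v <- rev(v)
    if (normalize) {
      if (v[1] == 0) { n_drop_zero <- n_drop_zero + 1L; next }
      v <- v / v[1]
    }
    rows[[length(rows) + 1L]] <- v
  }
  if (!length(rows)) {
    abort("no anchors survive window extraction", class = "nucspacing_error")
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- offs
  avg <- tibble(offset = offs, occupancy = unname(colMeans(mat)))
  structure(
    list(matrix = mat, average = avg, n_used = nrow(mat),
         n_dropped_window = n_drop_win, n_dropped_zero = n_drop_zero,
         window = window),
    class = "profile_matrix"
  )
}

#' Sort the rows of a profile matrix by mean occupancy in a region
#'
#' Rows are reordered by descending mean occupancy over the given offset
#' region (clipped to the matrix window); ties keep their original order
#' (stable sort). Used to produce ordered occupancy heat maps.
#'
#' @param x A `profile_matrix` or a plain matrix with offset column names.
#' @param region Length-2 offset bounds (default `c(-2000, 2000)`).
#' @return Same type as the input, rows reordered.
#' @export
sort_matrix_by_mean <- function(x, region = c(-2000, 2000)) {
  mat <- if (inherits(x, "profile_matrix")) x$matrix else x
  offs <- as.integer(colnames(mat))
  sel <- offs >= region[1] & offs <= region[2]
  if (!any(sel)) stop_bad_arg("region", "does not overlap the matrix window")
  m <- rowMeans(mat[, sel, drop = FALSE])
  ord <- order(-m)        # order() is a stable sort
  if (inherits(x, "profile_matrix")) {
    x$matrix <- mat[ord, , drop = FALSE]
    x
  } else {
    mat[ord, , drop = FALSE]
  }
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d anchors x %d offsets [%d, %d]\n",
              nrow(x$matrix), ncol(x$matrix), x$window[1], x$window[2]))
  cat(sprintf("  dropped: %d (incomplete window), %d (zero at leftmost)\n",
              x$n_dropped_window, x$n_dropped_zero))
  invisible(x)
}

#' @describeIn extract_profile_matrix Long tibble (anchor, offset, occupancy).
#' @param x A `profile_matrix`.
#' @param ... Unused.
#' @export
tidy.profile_matrix <- function(x, ...) {
  out <- tidyr::expand_grid(anchor = seq_len(nrow(x$matrix)),
                            offset = as.integer(colnames(x$matrix)))
  out$occupancy <- as.vector(t(x$matrix))
  out
}

#' @describeIn extract_profile_matrix One-row summary with anchor counts.
#' @export
glance.profile_matrix <- function(x, ...) {
  tibble(n_used = x$n_used, n_dropped_window = x$n_dropped_window,
         n_dropped_zero = x$n_dropped_zero,
         window_lower = x$window[1], window_upper = x$window[2])
}
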