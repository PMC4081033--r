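# Internal helpers shared across modules.

# Scalar checks ---------------------------------------------------------------

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_bad_arg <- function(arg, msg) {
  abort(sprintf("`%s` %s", arg, msg), class = "nucspacing_error")
}

# Extract a per-position numeric signal from a vector or a data frame.
# Data frames use `col` when present, otherwise the last numeric column.
as_profile <- function(x, col = "occupancy", arg = "profile") {
  if (is.data.frame(x)) {
    if (col %in% names(x)) {
      v <- x[[col]]
    } else {
      num <- vapply(x, is.numeric, logical(1))
      if (!any(num)) stop_bad_arg(arg, "has no numeric column")
      v <- x[[which(num)[sum(num)]]]
    }
  } else {
    v <- x
  }
  if (!is.numeric(v)) stop_bad_arg(arg, "must be numeric")
  as.numeric(v)
}

# Seeded evaluation that leaves the global RNG state untouched.
with_local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
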