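# Readers and writers for the standard formats the package consumes:
# bedGraph/BED through rtracklayer, FASTA through Biostrings, plain TSV
# through readr, model configurations as YAML.

#' Read a per-position affinity or energy track
#'
#' Accepts a 2-column TSV (`position`, `value`; 1-based positions) or a
#' bedGraph (decided by the file extension, or forced with `format`).
#' Positions absent from the file get `fill` (default 1 for affinities).
#'
#' @param path File path.
#' @param length Track length N; defaults to the largest position present.
#' @param format `"auto"`, `"tsv"` or `"bedgraph"`.
#' @param fill Value for positions not covered by the file.
#' @return Numeric vector of length `length`.
#' @export
read_affinity_track <- function(path, length = NULL,
                                format = c("auto", "tsv", "bedgraph"),
                                fill = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) {
      "bedgraph"
    } else "tsv"
  }
  if (format == "bedgraph") {
    tracks <- read_occupancy_bedgraph(path, fill = fill)
    v <- tracks[[1L]]
    if (!is.null(length)) {
      v <- c(v, rep(fill, max(0L, length - base::length(v))))[seq_len(length)]
    }
    return(v)
  }
  df <- readr::read_tsv(path, col_names = c("position", "value"),
                        comment = "#", show_col_types = FALSE)
  if (is.character(df$position[1]) && is.na(suppressWarnings(as.numeric(df$position[1])))) {
    df <- df[-1L, , drop = FALSE]       # header line
  }
  pos <- as.integer(df$position); val <- as.numeric(df$value)
  if (anyNA(pos) || anyNA(val) || any(pos < 1L)) {
    stop_bad_arg("path", "must contain 1-based positions and numeric values")
  }
  N <- length %||% max(pos)
  out <- rep(fill, N)
  keep <- pos <= N
  out[pos[keep]] <- val[keep]
  out
}

#' Read a bedGraph occupancy track into per-chromosome vectors
#'
#' @param path bedGraph file path.
#' @param fill Value for positions without coverage (default 0).
#' @return Named list of numeric vectors (1-based positions per chromosome).
#' @export
read_occupancy_bedgraph <- function(path, fill = 0) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- list()
  for (chr in as.character(GenomicRanges::seqnames(GenomicRanges::seqinfo(gr)))) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
    if (!base::length(sub)) next
    n <- max(GenomicRanges::end(sub))
    v <- rep(fill, n)
    st <- GenomicRanges::start(sub); en <- GenomicRanges::end(sub)
    sc <- sub$score
    for (i in seq_along(sub)) v[st[i]:en[i]] <- sc[i]
    out[[chr]] <- v
  }
  out
}

#' Write per-species coverage as bedGraph files
#'
#' One file per species, named `<prefix>.<species>.bedGraph`, with runs of
#' equal coverage merged into intervals (standard bedGraph 0-based,
#' half-open convention).
#'
#' @param solution A `lattice_solution`.
#' @param prefix Output path prefix.
#' @param chrom Chromosome name used in the output (default `"lattice"`).
#' @param digits Score rounding (default 6).
#' @return Invisibly, the written file paths.
#' @export
write_coverage_bedgraph <- function(solution, prefix, chrom = "lattice",
                                    digits = 6) {
  stopifnot(inherits(solution, "lattice_solution"))
  paths <- character(0)
  for (g in solution$species) {
    v <- round(solution$coverage[, g], digits)
    r <- rle(v)
    en <- cumsum(r$lengths)
    st <- en - r$lengths          # 0-based starts
    df <- data.frame(chrom = chrom, start = st, end = en, score = r$values)
    p <- sprintf("%s.%s.bedGraph", prefix, g)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read anchor positions from a BED file
#'
#' Uses the interval midpoint as the anchor summit (for 1-bp summit BED
#' files this is the summit itself). Returns 1-based positions.
#'
#' @param path BED file path.
#' @return Tibble with columns `chrom`, `position`, `strand`.
#' @export
read_bed_anchors <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    position = as.integer(floor((GenomicRanges::start(gr) +
                                   GenomicRanges::end(gr)) / 2)),
    strand = {
      s <- as.character(GenomicRanges::strand(gr))
      ifelse(s == "*", "+", s)
    }
  )
}

#' Read a fragment table (BED or 3-column TSV)
#'
#' BED input uses the standard 0-based half-open convention directly; TSV
#' input must have columns `left`, `right` and optionally `count` (rows are
#' replicated by count).
#'
#' @param path File path.
#' @return Tibble with columns `left`, `right`, `length`.
#' @export
read_fragments <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    left <- GenomicRanges::start(gr) - 1L      # back to 0-based
    right <- GenomicRanges::end(gr)
    return(tibble(left = left, right = right, length = right - left))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("left", "right") %in% names(df))) {
    names(df)[1:2] <- c("left", "right")
  }
  if ("count" %in% names(df)) {
    df <- df[rep(seq_len(nrow(df)), df$count), , drop = FALSE]
  }
  tibble(left = as.integer(df$left), right = as.integer(df$right),
         length = as.integer(df$right - df$left))
}

#' Write a DNA sequence as FASTA
#'
#' @param sequence DNA string.
#' @param path Output path.
#' @param name Sequence header.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequence, path, name = "sequence") {
  x <- Biostrings::DNAStringSet(as.character(sequence))
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read the first sequence of a FASTA file as a character string
#'
#' @param path FASTA path.
#' @return Character DNA string.
#' @export
read_fasta_sequence <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (!base::length(x)) stop_bad_arg("path", "contains no sequence")
  as.character(x[[1L]])
}

# Model configuration (YAML) --------------------------------------------------

#' Read a lattice model from a YAML configuration
#'
#' The configuration mirrors the model constructors: top-level `N` and
#' optional `boundary`; a `species` list whose entries have `id`,
#' `footprint`, and either `activity` or `binding_constant` +
#' `concentration`, optional `unwrap: {h_max, per_bp_penalty}` and
#' `is_nucleosome`; optional `interactions` entries with `g1`, `g2` and one
#' of `omega` (contact), `V` (hard exclusion) or `w_values`; an optional
#' `linker_cap` block; and an optional `affinity` map of species id to a
#' track file path (resolved relative to the configuration file).
#'
#' @param path YAML file path.
#' @return A [lattice_model()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads an unquoted key `N` as the boolean FALSE; accept that
  # spelling as well as a quoted "N" or the alias `length`
  if (is.null(cfg$N)) cfg$N <- cfg$length %||% cfg[["FALSE"]]
  for (key in c("N", "species")) {
    if (is.null(cfg[[key]])) {
      abort(sprintf("model configuration is missing required key '%s'", key),
            class = "nucspacing_config_error")
    }
  }
  # YAML parses exponents without a sign ("2e9") as strings; coerce
  num <- function(x) if (is.character(x)) as.numeric(x) else x
  species <- lapply(cfg$species, function(s) {
    if (is.null(s$id) || is.null(s$footprint)) {
      abort("species entry needs 'id' and 'footprint'",
            class = "nucspacing_config_error")
    }
    unwrap <- if (!is.null(s$unwrap)) {
      unwrap_spec(num(s$unwrap$h_max), num(s$unwrap$per_bp_penalty) %||% 1)
    }
    species_spec(s$id, num(s$footprint), activity = num(s$activity),
                 binding_constant = num(s$binding_constant),
                 concentration = num(s$concentration), unwrap = unwrap,
                 is_nucleosome = s$is_nucleosome %||% (s$footprint == 147))
  })
  interactions <- lapply(cfg$interactions %||% list(), function(r) {
    if (!is.null(r$omega)) contact_cooperativity(r$g1, r$g2, r$omega)
    else if (!is.null(r$V)) hard_exclusion(r$g1, r$g2, r$V)
    else interaction_rule(r$g1, r$g2, as.numeric(unlist(r$w_values)))
  })
  linker_cap <- if (!is.null(cfg$linker_cap)) {
    lc <- cfg$linker_cap
    linker_cap_rule(lc$linker, lc$nucleosome, cap = lc$cap %||% 1L,
                    vicinity = lc$vicinity %||% 0L,
                    allow_free_binding = isTRUE(lc$allow_free_binding))
  }
  affinity <- list()
  for (id in names(cfg$affinity %||% list())) {
    p <- cfg$affinity[[id]]
    if (!file.exists(p)) p <- file.path(dirname(path), cfg$affinity[[id]])
    affinity[[id]] <- read_affinity_track(p, length = cfg$N)
  }
  lattice_model(cfg$N, species, affinity = affinity,
                interactions = interactions, linker_cap = linker_cap,
                boundary = cfg$boundary %||% "hard_wall")
}
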