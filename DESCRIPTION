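Package: nucspacing
Title: Lattice Models of Nucleosome Spacing and Repeat-Length Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact equilibrium solvers for generalized one-dimensional lattice
    models of competitive multi-protein binding to DNA, including partial
    nucleosome unwrapping, contact and finite-range internucleosome
    interactions, and linker-histone stoichiometry rules. Provides nucleosome
    repeat length (NRL) estimation by peak-position regression, parameter
    scans, sequence-derived affinity tracks with polynomial-detrend Fourier
    periodicity analysis, anchor-centred aggregate occupancy profiles, and
    cyclic-coordinate fragment analyses for tandem repeats such as the mouse
    major satellite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
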