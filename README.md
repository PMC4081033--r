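# nucspacing

Exact 1D lattice models of competitive multi-protein binding to DNA, built
for one question: what sets the **nucleosome repeat length (NRL)** — the
average center-to-center distance between neighbouring nucleosomes — and how
does it respond to DNA sequence, protein concentrations, partial nucleosome
unwrapping, and short- and long-range internucleosome interactions?

The package is aimed at chromatin biophysicists and computational
epigenomicists who want to go beyond hard-rod "statistical positioning"
cartoons without writing a transfer-matrix solver from scratch, and at
analysts of MNase-seq data who need the standard companion analyses
(boundary-anchored NRL fits, aggregate profiles, tandem-repeat fragment
phasing) under one roof.

## The model

DNA is a lattice of `N` bp units. Each species `g` (histone octamer, linker
histone, transcription factor, ...) covers `m(g)` bp when bound, with
per-particle statistical weight

```
a(g) * K(n, g) * eps^(h1 + h2)
```

— dimensionless activity `a = K * c0`, position-specific relative binding
constant `K(n, g)` anchored at the nominal frame start, and an optional
unwrapping penalty for peeling `h1 + h2 <= h_max` bp off the particle ends.
Nearest bound neighbours at uncovered gap `L` contribute a pairwise weight
`w(L, g1, g2)`; contact cooperativity (`w(0) = omega`) and hard exclusion
(`w(L < V) = 0`, the long-range anticooperativity) are the two classical
limits. A chromatosome stoichiometry rule caps bound linker histones per
nucleosome. `lattice_solve()` returns exact Boltzmann-ensemble marginals
(per-species coverage `c(g, n)`, frame-start probabilities, free fraction,
log partition function) by dynamic programming — no sampling — and
`brute_force_solve()` is an independent enumeration oracle that the solver
is tested against to 1e-9.

The NRL is then read off the way it is measured experimentally: occupancy
oscillations next to a boundary are peak-called and the slope of peak
position versus peak index is the repeat length (`find_occupancy_peaks()`,
`fit_nrl()`, `occupancy_nrl()`, `scan_nrl()`).

## Worked example

A 4000-bp lattice of nucleosomes at activity 0.7 with a 30-bp exclusion zone
between neighbours — the configuration that reproduces in-vivo-like spacing
at yeast promoters:

```r
library(nucspacing)

m <- lattice_model(4000, species_spec("NCP", 147, activity = 0.7),
                   interactions = list(hard_exclusion("NCP", "NCP", 30)))
sol <- lattice_solve(m)
sol
#> <lattice_solution> N = 4000 bp (hard_wall), log Z = 79.5459
#>   NCP: mean coverage 0.6485, expected particles 17.645

occupancy_nrl(m)
#> <nrl_estimate> NRL = 205.51 bp (se 2.55, r^2 0.99938, 6 peaks)
```

The lattice holds ~17.6 nucleosomes covering 65% of the DNA; six occupancy
peaks march away from the boundary with a fitted repeat of 205.5 bp —
177 bp of minimum center spacing (147 + 30) plus the entropic gap at this
density. Without the exclusion rule the same density gives ~169 bp. Results
are tibble-friendly (`tidy()`, `glance()`) and plottable (`autoplot()`).

Sequence-driven positioning on mouse pericentric heterochromatin repeats:

```r
satellite_nrl()
#> <nrl_estimate> NRL = 234.01 bp (se 0.00689, r^2 1.00000, 46 peaks)
```

Fifty tandem copies of the 234-bp major satellite unit, scored by a
sequence-affinity surrogate and solved in the sequence-dominant regime,
phase nucleosomes at exactly one per repeat unit — the repeat length the
sequence alone would dictate (experimentally, heterochromatin ignores this
preference; the fragment-analysis functions `wrap_fragments()`,
`end_frequency_profile()` and `autocorr_period()` implement the cyclic
coordinate analyses that show the 10-bp start-site phasing instead).

Linker-histone titration of the NRL under the one-per-nucleosome
chromatosome rule:

```r
scan <- linker_titration_scan(linker_titration_grid())
steepest_doubling(scan)
#> # A tibble: 1 x 5
#>   activity_low activity_high nrl_low nrl_high delta_nrl
#>          <dbl>         <dbl>   <dbl>    <dbl>     <dbl>
#> 1        0.075          0.15    177.     183.      6.01
```

The titration rises from ~169 bp and saturates near 192 bp; in the middle of
the stoichiometric transition, doubling the linker-to-core ratio shifts the
NRL by ~6 bp.

A thin command-line wrapper over the same functions ships at
`inst/cli/nucspacing.R` (subcommands `solve`, `nrl`, `scan`, `seq2aff`,
`period`, `aggregate`, `repeats`, `simulate`), for running models and
analyses from a shell with provenance-stamped outputs.

See the methods vignette (`vignettes/nucleosome-spacing-model.Rmd`) for the
model conventions, solver internals, estimator design and the rationale
behind every default.

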