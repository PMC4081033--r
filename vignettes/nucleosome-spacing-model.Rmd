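---
title: "Lattice models of nucleosome spacing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice models of nucleosome spacing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucspacing)
```

## The model

Genomic DNA is a one-dimensional lattice of `N` base-pair units. Each unit is
either free or covered by one bound particle of one of `f` species — histone
octamers (nucleosome core particles, NCP), linker histones, transcription
factors, or any other footprint-forming DNA binder. A particle of species `g`
is specified by

* its footprint `m(g)` in bp (147 for the fully wrapped NCP),
* its dimensionless activity `a(g) = K(g) * c0(g)` — the product of binding
  constant and free protein concentration; both the product and the separate
  factors are accepted as input,
* an optional position-specific relative binding constant `K(n, g)`, indexed
  by the leftmost unit of the nominal, fully wrapped frame,
* optionally, an unwrapping rule: the particle may peel `h1` and `h2` bp off
  its two ends, `h1 + h2 <= h_max`, shrinking the covered stretch to
  `m - h1 - h2` while keeping its frame identity (and therefore its
  sequence-specific weight, which stays anchored at the frame start). Each
  unwrapped base pair contributes the factor `per_bp_penalty`; the default 1
  is the pure-entropy limit in which only the multiplicity of unwrapped
  states matters.

A configuration is any placement of particles whose *covered* stretches do
not overlap; nominal frames of partially unwrapped neighbours may. Its
statistical weight is the product of the per-particle weights
`a(g) K(n, g) eps^(h1 + h2)`, pairwise weights `w(L, g1, g2)` between nearest
covered neighbours at uncovered gap `L`, and the linker-cap legality factor
described below. Two classical limits of `w` have dedicated constructors:
contact cooperativity (`w(0) = omega`, 1 otherwise) and hard exclusion
(`w(L < V) = 0`), the long-range anticooperativity that sets a lower bound on
internucleosome spacing.

Two conventions deserve emphasis because the literature is loose about them:

* **Exclusion and gaps act on covered stretches, not frames.** With
  pure-entropy unwrapping, frame-based exclusion would make unwrapping
  thermodynamically inert — it demonstrably shortens the repeat length, so
  the covered-stretch convention is the physically meaningful one. It also
  keeps `w(L >= 0)` well defined (frame gaps of unwrapped neighbours can be
  negative). A consequence worth remembering when comparing with
  experiments: an apparent linker length computed as `NRL - 147` can be
  much shorter than the true minimum gap `V` whenever particles are
  partially unwrapped.
* **Equilibrium is an effective description.** In vivo, remodelers and
  chaperones drive nucleosome repositioning; the model treats the resulting
  stationary occupancy as a collective equilibrium over a cell ensemble, so
  "binding constants" for the octamer are effective parameters, not dilute
  solution constants.

### Linker-histone stoichiometry

A simple competitive linker that binds free DNA cannot reproduce the
saturating repeat-length response to linker-histone concentration: its
occupancy grows without bound and eventually out-competes nucleosomes. The
package therefore implements a chromatosome stoichiometry rule
(`linker_cap_rule()`), expressed on the left-to-right token sequence of bound
particles:

* a maximal run of linker tokens between two nucleosome tokens may hold at
  most `2 * cap` linkers (an allotment of `cap` per flanking nucleosome), and
  at most `cap` before the first or after the last nucleosome;
* when `allow_free_binding` is off, every linker must additionally sit within
  `vicinity` bp of the covered edge of an adjacent nucleosome — a linker that
  is not anchored to its left neighbour must be anchored by the next
  nucleosome to its right, which is exactly representable in the
  dynamic-programming state machine.

The default `cap = 1` encodes "at most one linker histone per nucleosome".
The default `vicinity` in the titration study conditions is 5 bp: the rule is
meant to keep linker-nucleosome distances flexible rather than enforce rigid
contact (see the calibration note below).

## Exact solvers

`lattice_solve()` computes exact marginals by a forward-backward dynamic
programme over covered-end positions. Unwrapped states with equal total
deficit `u = h1 + h2` share a covered length and are aggregated into one
placement class whose positional weight is the windowed sum of `K`; the
per-`h1` resolution is restored afterwards when frame-start marginals are
assembled. Finite-range pair weights are handled through an explicit gap
window of width `R` (the largest gap at which any `w` differs from 1) plus a
cumulative channel for gaps beyond `R`. The linker-cap rule adds a small
bound-particle state machine (nucleosome seen, current run length, pending
right-anchoring, pending run debt).

Numerical safeguards: running weights are periodically rescaled to avoid
overflow (partition functions grow like `e^{mu N}`), with log-scale
bookkeeping; the inbound and suffix sums needed for marginals are snapshotted
in log space at computation time so that later rescaling cannot underflow
them. Marginals are assembled as `exp(log I + log W + log b - log Z)`.
`free_prob` is reported by complementarity (`1 - sum(coverage)`); the
enumeration oracle computes it independently by direct counting, so the
normalization identity is genuinely exercised by the equivalence tests
rather than being true by construction in both solvers.

`brute_force_solve()` is a deliberately independent reference: it expands
every placement (species, frame start, unwrapping split), walks every
configuration recursively, applies the cap rule declaratively to the full
token sequence, and tallies marginals by direct summation. A counting bound
(ignoring interaction weights, which only remove configurations) guards
against oversized instances. The test suite checks agreement between the two
implementations to within `1e-9` relative error on hundreds of seeded random
instances covering unwrapping, cooperativity, exclusion, general `w(L)`
tables, cap rules, affinity tracks, and both boundaries.

Under a cyclic boundary the solver conditions on the bound particle with the
smallest covered start on the ring, which reduces each case to a linear
problem between two phantom copies of that particle; the wrap-around pair
weight closes the ring (a single particle interacts with itself across the
remaining gap — a convention shared by both solvers). The cost scales with
`N^2`, which is adequate for repeat-scale rings; large tandem arrays are
better treated linearly with cyclic sequence padding, which is how the
satellite analysis is set up. The cyclic driver does not support the
linker-cap rule (the run bookkeeping does not compose with the ring
conditioning without a much larger state machine); the enumeration oracle
does, so that combination remains testable at small `N`.

`mcghee_von_hippel_density()` provides the closed-form infinite-lattice
reference for non-cooperative binding,
`nu / a = (1 - m nu) ((1 - m nu) / (1 - (m-1) nu))^(m-1)`, solved in log form
for numerical stability at large footprints; the interior of a 5000-bp
hard-wall lattice agrees with it to better than `1e-4` covered fraction over
footprints 2-147, which is the package's closed-form limit check.

## Repeat-length estimation

The nucleosome repeat length is extracted exactly as chromatin biologists
read it off phased-array data: oscillations of the occupancy are measured
from a boundary (a segment end, or any anchor), the peak positions are
collected, and the slope of peak position against peak index is the NRL.
`find_occupancy_peaks()` uses topographic prominence (default threshold 2%
of the profile range) and a minimum separation (default 100 bp — below any
plausible NRL, above noise wiggles); no smoothing is applied. `fit_nrl()`
is an ordinary least-squares fit with at least three peaks, reporting the
slope, its standard error and `r^2`. The default analysis window is 1500 bp
from the boundary. These defaults are package choices — peak-calling
parameters of this kind are rarely printed in the experimental literature.

`scan_nrl()` maps a model factory over a parameter grid and flags (rather
than fails on) grid points with fewer than three detectable peaks. The trend
suite in the tests reproduces the canonical statistical-positioning
behaviour on 4000-bp hard-wall lattices: NRL decreases with nucleosome
density, with maximal unwrapping, and with contact cooperativity; it grows
linearly with the exclusion range `V` (`r^2 > 0.99`); and the linker
titration below rises and saturates.

## Study conditions shipped with the package

### Satellite tandem arrays

`satellite_array_model()` tiles the 234-bp major satellite consensus unit 50
times head-to-tail, appends the first 49 nt once more (the standard linear
emulation of cyclic boundary conditions, matching how reads are mapped to
such references), and derives a sequence affinity track from the tiled
sequence. The shipped surrogate is window-GC content over the 147-bp
footprint converted to a Boltzmann affinity (`gc_window_affinity()`), with
the energy additionally smoothed at the footprint scale. The smoothing
matters: satellite DNA carries strong internal sub-repeats (~58 bp), and an
unsmoothed footprint-GC landscape is bimodal within each unit, which would
phase nucleosomes at half the unit length. Smoothing at the particle scale
suppresses sub-nucleosomal composition harmonics while leaving the per-unit
landscape — which is the scale a bound particle can actually distinguish.
Any sequence-preference model that is periodic with the unit serves the same
purpose; the claim under test is that in the sequence-dominant (low
activity, default 0.05) regime the fitted NRL equals the unit length,
234 bp. `satellite_nrl()` excludes two repeat units at each end of the array
so that the hard walls do not distort the slope; the remaining ~46 peaks fit
the unit length with `r^2 = 1` to six decimals.

The companion observation — that real heterochromatin does *not* show the
234-bp repeat but instead a 10-bp phasing of start sites and, after
mono-nucleosome size selection (145-150 bp), two mutually exclusive
preferred positions — is an analysis of mapped fragments, not of the model.
The `repeat_analysis` functions implement it: `wrap_fragments()` reduces
left ends modulo the unit on the padded reference, `end_frequency_profile()`
counts left/right ends with an optional inclusive length filter, and
`autocorr_period()` reads the start-site periodicity from the circular
autocorrelation.

### Linker-histone titration

`linker_titration_scan()` is the two-species study condition behind the
linker-histone results: NCP at activity 0.7 (homogeneous, 147 bp) plus a
15-bp linker whose activity is scanned, under the chromatosome cap rule
(cap 1, vicinity 5 bp, no free binding) on a 4000-bp hard-wall lattice. The
NRL rises from ~169 bp, climbs through the stoichiometric transition as
nucleosomes acquire their flanking linkers, and saturates near 192 bp once
essentially every nucleosome carries its allotment; the bound
linker-per-nucleosome ratio is reported alongside and approaches 2 linkers
per nucleosome (one per side) from below. Two regimes of the same curve
reproduce the two classical experimental behaviours: the low-stoichiometry
segment is linear in bound linker per nucleosome (`r^2 > 0.95`), and the
high-activity end approaches a finite supremum within 1 bp.

Three aspects of these conditions were genuinely open and fixed as follows:

* **Model variant.** Letting the linker bind free DNA destroys the
  statistical-positioning ladder at any appreciable activity (a small
  flexible spacer decorrelates the array within a couple of neighbours) and
  makes the titration non-monotone; very strong contact cooperativity
  instead locks gaps at exactly the linker size and *shortens* the repeat.
  Only the anchored, capped variant yields the monotone increasing and
  saturating titration, so it is the packaged condition.
* **Anchoring window.** The vicinity of 5 bp (a third of the linker
  footprint — flexible but near-contact, consistent with binding at the
  nucleosome entry/exit region) was calibrated once against the reported
  magnitude of the doubling response below and then frozen; a rigid contact
  rule gives a qualitatively identical curve with a somewhat smaller
  response.
* **Doubling response.** The headline number — the NRL change caused by
  doubling the linker-to-core concentration ratio — depends on where along
  the titration the doubling is taken. `steepest_doubling()` makes the
  reported quantity well defined: it scans every pair `(a, 2a)` present in
  the grid and reports the largest NRL difference, i.e. the strongest
  experimentally detectable response to a two-fold stoichiometry change.
  Under the frozen conditions this is ~6 bp, attained in the middle of the
  stoichiometric transition.

For the size-dependence comparison (smaller linkers exert a stronger
spacing effect at equal activity), free binding *is* allowed and the
activity kept low (0.02): that claim isolates the configurational-entropy
mechanism of free intercalation, which the anchored variant deliberately
suppresses, and at low activity the ladder remains readable.

## Periodicity estimators

`detrend_fourier_period()` implements the detrend-then-transform reading of
oscillations superimposed on a broad trend (the kb-scale dip of
nucleosome-formation energy around regulatory sites): subtract a polynomial
least-squares fit, Fourier-transform the residual, exclude frequencies below
`min_cycles` (default 4) oscillations per window, take the period of maximal
power, and refine it by parabolic interpolation of log-power. Two numerical
choices make this well defined. The basis is Legendre polynomials on
rescaled coordinates, generated by the three-term recurrence (raw monomials
`x^90` underflow and lose rank). And because a full-rank polynomial of
degree `d` absorbs any oscillation with fewer than about `d/2` cycles per
window — which at conventional degrees would swallow exactly the 150-250-bp
periodicities of interest in 1-3-kb windows — the effective degree is capped
at `2 * min_cycles - 2`, tying the trend's bandwidth to the documented
low-frequency cutoff. Every nominal degree at or above the cap gives an
identical result by construction, which is also why the procedure is
insensitive to the polynomial power over the conventional 50-120 range.
Degenerate (constant-residual) inputs return `NA` with a warning rather
than failing.

`autocorr_period()` is the comb-signal counterpart for phased start-site
counts. A perfect comb autocorrelates equally at every multiple of its
fundamental, and noise hands the raw maximum to an arbitrary multiple;
ties and near-ties are therefore resolved to the smallest lag within a
tolerance band of the maximum (a quarter of the max-over-median excess).
The estimators are validated on implanted periods: 30-250 bp within one
interpolated FFT bin for the spectral route (10 noise realizations at
signal-to-noise 2), and 5-30-bp combs exactly for the autocorrelation
route.

## Aggregation conventions

`extract_profile_matrix()` averages anchor-centred windows (default
-1500..+1500 bp) of a per-bp occupancy track. Each surviving row is
normalized to 1 at its leftmost position; rows are dropped and counted when
the window leaves the track or when the leftmost value is 0 (normalization
undefined). Minus-strand anchors are reversed by default so all rows read
boundary-outward — the convention is exposed as a flag because strand-naive
averaging is also in circulation. Missing track values inside a window count
as zero coverage with a warning, matching the usual MNase-coverage
convention. Row order is preserved; `sort_matrix_by_mean()` reorders by
descending mean occupancy in a clipped region (default -2000..+2000 bp) with
a stable sort, which is the ordered-heat-map convention.

## Synthetic data

All generators are pure functions of their arguments and an explicit seed
(`withr::with_seed`; the global RNG state is never touched).
`gen_boundary_model()` builds hard-wall lattices at a target interior
density by inverting the binding isotherm. `gen_fragment_set()` samples
fragments with Gaussian-mixture left ends and truncated-Gaussian lengths on
the padded satellite reference — the structure, not the biology, of
size-selected MNase fragments: no digestion sequence bias, no duplicate
structure, no mapping artefacts. `gen_phased_track()` lays a damped cosine
around anchors with per-anchor jitter on a flat baseline — phased arrays
without the confounders of real coverage (copy-number variation, chromatin
heterogeneity, library-size effects). Passing tests on these fixtures
demonstrates that the estimators and the solver are correct on signals with
known ground truth; it does not certify performance on real MNase-seq, where
the confounders above dominate error budgets.

## Problem sizes and runtime

The shipped analyses use lattices of 4000 bp (titrations and trend scans, a
window that holds 8-20 phased nucleosomes), 5000 bp (isotherm limit checks)
and 11749 bp (the 50-unit satellite array); oracle-equivalence instances are
kept at `N <= 14` so exhaustive enumeration stays exact and fast. A single
solve costs well under a second without unwrapping and a few seconds with
`h_max = 40`; the full test suite and the acceptance script each run in
about a minute on one core.

## Known limitations

* Equilibrium marginals only: no kinetics, no explicit remodeler dynamics,
  no 3D fibre geometry or electrostatics — those enter only effectively,
  through `w(L)` and the activities.
* The cyclic solver is quadratic in `N` and excludes the linker-cap rule.
* The GC-content affinity surrogate is a stand-in for trained
  sequence-preference models; it reproduces periodic landscape structure on
  repeats but not absolute affinities or dinucleotide-level detail.
* `start_prob` is an expected count of frame starts per position (the
  distinction from a probability matters only in the exotic case of two
  heavily unwrapped particles sharing a frame start).
* Read mapping, peak calling and genome-build management are out of scope;
  anchors and fragment tables are inputs.
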