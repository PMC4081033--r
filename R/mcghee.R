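#' McGhee-von Hippel occupancy density for large non-cooperative lattices
#'
#' Solves the classical binding isotherm for a ligand covering `footprint`
#' lattice units at dimensionless activity `a` on an infinite homogeneous
#' lattice,
#' \deqn{\nu / a = (1 - m\nu) \left(\frac{1 - m\nu}{1 - (m - 1)\nu}\right)^{m-1},}
#' where \eqn{\nu} is the bound-particle density per lattice unit. The
#' product `footprint * nu` is the covered fraction, which is what the
#' interior of a long hard-wall lattice converges to; this closed-form limit
#' is the reference against which the exact solver is validated.
#'
#' @param footprint Ligand footprint m in lattice units (>= 1).
#' @param activity Dimensionless activity `K * c0` (>= 0).
#' @return Bound-particle density `nu` per lattice unit, in `[0, 1/m]`.
#' @examples
#' mcghee_von_hippel_density(1, 1)     # Langmuir: a / (1 + a) = 0.5
#' 147 * mcghee_von_hippel_density(147, 0.7)  # covered fraction
#' @export
mcghee_von_hippel_density <- function(footprint, activity) {
  if (!is_count(footprint, min = 1L)) stop_bad_arg("footprint", "must be a positive integer")
  if (!is_number(activity) || activity < 0) stop_bad_arg("activity", "must be non-negative")
  m <- as.double(footprint)
  if (activity == 0) return(0)
  fn <- function(nu) {
    # log form is stable for large m
    log(nu) - log(activity) - log1p(-m * nu) -
      (m - 1) * (log1p(-m * nu) - log1p(-(m - 1) * nu))
  }
  upper <- 1 / m * (1 - 1e-12)
  lower <- min(1e-300, upper / 2)
  flo <- fn(lower); fhi <- fn(upper)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    abort("no root of the binding isotherm in [0, 1/m]",
          class = "nucspacing_numerical_error")
  }
  uniroot(fn, c(lower, upper), tol = .Machine$double.eps^0.75)$root
}

#' Invert the isotherm: activity needed for a target covered fraction
#'
#' @param footprint Ligand footprint in lattice units.
#' @param coverage Target covered fraction `m * nu` in (0, 1).
#' @return The dimensionless activity whose isotherm density covers
#'   `coverage` of the lattice.
#' @export
mcghee_von_hippel_activity <- function(footprint, coverage) {
  if (!is_number(coverage) || coverage <= 0 || coverage >= 1) {
    stop_bad_arg("coverage", "must be in (0, 1)")
  }
  m <- as.double(footprint)
  nu <- coverage / m
  # direct inversion of the isotherm
  exp(log(nu) - log1p(-m * nu) -
        (m - 1) * (log1p(-m * nu) - log1p(-(m - 1) * nu)))
}
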