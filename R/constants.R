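# Physical constants in the unit system used throughout: lengths in Angstrom,
# energies in kcal/mol, concentrations in mol/L, times in ps.

#' Physical constants used by kpore
#'
#' A named list of the constants the package computes with:
#' \describe{
#'   \item{kB}{Boltzmann constant, 0.0019872 kcal/(mol K).}
#'   \item{coulomb}{e^2/(4 pi eps0) = 332.0637 kcal A/mol, so that the
#'     interaction of two unit charges at distance r Angstrom in a medium of
#'     relative permittivity eps is \code{332.0637/(eps*r)} kcal/mol.}
#'   \item{molar_to_A3}{conversion from mol/L to particles per cubic
#'     Angstrom (Avogadro constant / 1e27).}
#'   \item{faraday_RT_300}{RT/F at 300 K in mV (25.8645 mV), used by the
#'     Goldman-Hodgkin-Katz relation.}
#' }
#' @export
kpore_constants <- list(
  kB          = 0.0019872,
  coulomb     = 332.0637,
  molar_to_A3 = 6.02214076e23 / 1e27,
  cc_bond     = 1.42,   # graphene C-C bond length, Angstrom
  co_bond     = 1.23,   # carbonyl C=O bond length, Angstrom
  r_cov_C     = 0.77,   # covalent radius of carbon, Angstrom
  r_cov_O     = 0.66    # covalent radius of oxygen, Angstrom
)

# RT/F in mV at temperature T (K)
rt_over_f_mV <- function(temperature) {
  # R = 8.31446 J/(mol K), F = 96485.33 C/mol -> RT/F in volts, x1000 for mV
  8.314462618 * temperature / 96485.33212 * 1000
}

# evaluate f() with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards; all generators funnel through this
with_seed <- function(seed, f) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  f()
}
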