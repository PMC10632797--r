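# Primitive-model electrolyte thermodynamics.
#
# Solutions are charged hard spheres in a dielectric continuum. The excess
# free energy has a hard-sphere part from the Mansoori-Carnahan-Starling-
# Leland (BMCSL) mixture equation of state and an electrostatic part from
# the non-restricted mean spherical approximation (MSA) evaluated through
# the energy route (the Debye charging process gives beta*A = beta*E +
# Gamma^3/(3 pi)). The direct mean-field Coulomb term vanishes for a
# homogeneous electroneutral reservoir. Chemical potentials are exact
# density gradients of the free-energy densities, so Gibbs-Duhem holds by
# construction.

#' Ion species table
#'
#' @param name species names.
#' @param valence signed integer charges.
#' @param hydrated_diameter hydrated diameters in Angstrom.
#' @return data.frame describing the species.
#' @export
ion_species <- function(name, valence, hydrated_diameter) {
  stopifnot(length(name) == length(valence),
            length(name) == length(hydrated_diameter),
            all(hydrated_diameter > 0))
  data.frame(name = name, valence = as.integer(valence),
             hydrated_diameter = hydrated_diameter)
}

#' Default K+/Na+/Cl- species with their hydrated diameters (5.6, 4.7 and
#' 6.4 Angstrom)
#' @export
default_species <- function() {
  ion_species(c("K", "Na", "Cl"), c(1L, 1L, -1L), c(5.6, 4.7, 6.4))
}

#' Electrolyte solution state
#'
#' @param concentrations named numeric vector of molar concentrations
#'   (mol/L), names matching the species table.
#' @param temperature K.
#' @param relative_permittivity dielectric constant of the solvent continuum
#'   (78.4: water at 300 K).
#' @param species an [ion_species()] table.
#' @param neutrality_tol allowed |sum z_i c_i| (mol/L).
#' @return object of class `solution_state`.
#' @export
solution_state <- function(concentrations, temperature = 300,
                           relative_permittivity = 78.4,
                           species = default_species(),
                           neutrality_tol = 1e-9) {
  stopifnot(all(names(concentrations) %in% species$name),
            all(concentrations >= 0), temperature > 0,
            relative_permittivity > 0)
  conc <- stats::setNames(numeric(nrow(species)), species$name)
  conc[names(concentrations)] <- concentrations
  net <- sum(species$valence * conc)
  if (abs(net) > neutrality_tol)
    stop(sprintf("state violates electroneutrality: sum z_i c_i = %.3g", net))
  structure(list(concentrations = conc, temperature = temperature,
                 relative_permittivity = relative_permittivity,
                 species = species),
            class = "solution_state")
}

#' @export
print.solution_state <- function(x, ...) {
  cat(sprintf("solution state at %g K, eps_r = %g: %s\n", x$temperature,
              x$relative_permittivity,
              paste(sprintf("%s %.4g M", names(x$concentrations),
                            x$concentrations), collapse = ", ")))
  invisible(x)
}

# Bjerrum length in Angstrom
bjerrum_length <- function(state) {
  kpore_constants$coulomb /
    (state$relative_permittivity * kpore_constants$kB * state$temperature)
}

# reduced moments xi_k = (pi/6) sum rho_i sigma_i^k, rho in 1/A^3
.xi <- function(rho, sigma, k) pi / 6 * sum(rho * sigma^k)

# BMCSL excess free-energy density, beta*A_ex/V in 1/A^3
bmcsl_f <- function(rho, sigma) {
  if (sum(rho) <= 0) return(0)
  x3 <- .xi(rho, sigma, 3)
  if (x3 >= 0.74) stop("unphysical packing: total packing fraction >= 0.74")
  x0 <- .xi(rho, sigma, 0); x1 <- .xi(rho, sigma, 1); x2 <- .xi(rho, sigma, 2)
  (6 / pi) * ((x2^3 / x3^2 - x0) * log(1 - x3) +
              3 * x1 * x2 / (1 - x3) + x2^3 / (x3 * (1 - x3)^2))
}

#' MSA screening parameter
#'
#' Solves the non-restricted MSA closure for the screening parameter Gamma
#' (1/Angstrom) by bracketed root finding on the interval from 0 to
#' kappa/2, where kappa is
#' the Debye parameter. For equal diameters sigma the solution reduces to
#' the restricted closed form (sqrt(1 + 2 kappa sigma) - 1) / (2 sigma).
#'
#' @param state a `solution_state`.
#' @param tol relative solver tolerance.
#' @return Gamma in 1/Angstrom.
#' @export
msa_gamma <- function(state, tol = 1e-13) {
  rho <- state$concentrations * kpore_constants$molar_to_A3
  msa_gamma_raw(rho, state$species$hydrated_diameter,
                state$species$valence, bjerrum_length(state), tol)
}

msa_gamma_raw <- function(rho, sigma, z, lB, tol = 1e-13) {
  if (all(rho * z^2 == 0)) return(0)
  Delta <- 1 - .xi(rho, sigma, 3)
  kappa <- sqrt(4 * pi * lB * sum(rho * z^2))
  resid <- function(G) {
    Omega <- 1 + pi / (2 * Delta) * sum(rho * sigma^3 / (1 + G * sigma))
    Pn <- sum(rho * sigma * z / (1 + G * sigma)) / Omega
    X <- (z - pi / (2 * Delta) * Pn * sigma^2) / (1 + G * sigma)
    G^2 - pi * lB * sum(rho * X^2)
  }
  # bracketed bisection on [0, kappa/2]: resid(0) < 0 <= resid(kappa/2)
  lo <- 0; hi <- kappa / 2 * (1 + 1e-9)
  f_lo <- resid(lo); f_hi <- resid(hi)
  if (f_lo > 0 || f_hi < 0) stop("MSA Gamma solver: bracket failure")
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- resid(mid)
    if (fm <= 0) { lo <- mid; f_lo <- fm } else { hi <- mid; f_hi <- fm }
    if ((hi - lo) <= tol * max(hi, 1)) break
  }
  (lo + hi) / 2
}

# MSA excess free-energy density via the energy route, beta*A_ex/V in 1/A^3
msa_f <- function(rho, sigma, z, lB) {
  G <- msa_gamma_raw(rho, sigma, z, lB)
  if (G == 0) return(0)
  Delta <- 1 - .xi(rho, sigma, 3)
  Omega <- 1 + pi / (2 * Delta) * sum(rho * sigma^3 / (1 + G * sigma))
  Pn <- sum(rho * sigma * z / (1 + G * sigma)) / Omega
  E <- -lB * (G * sum(rho * z^2 / (1 + G * sigma)) +
              pi / (2 * Delta) * Pn * sum(rho * z * sigma / (1 + G * sigma)))
  E + G^3 / (3 * pi)
}

# d f / d rho_i by central difference (forward at rho_i = 0); f takes rho
density_gradient <- function(f, rho, i, rel_step = 1e-5) {
  h <- max(rho[i] * rel_step, 1e-10)
  rp <- rho; rp[i] <- rho[i] + h
  rm <- rho; rm[i] <- max(rho[i] - h, 0)
  unname((f(rp) - f(rm)) / (rp[i] - rm[i]))
}

.species_index <- function(state, species) {
  i <- match(species, state$species$name)
  if (is.na(i)) stop(sprintf("unknown species '%s'", species))
  i
}

#' Ideal chemical potential
#'
#' kB T ln(c / c0) with c0 = 1 mol/L.
#' @param state a `solution_state`.
#' @param species species name.
#' @return kcal/mol.
#' @export
ideal_mu <- function(state, species) {
  i <- .species_index(state, species)
  c_i <- state$concentrations[[i]]
  if (c_i <= 0) stop("ideal_mu undefined at zero concentration")
  kpore_constants$kB * state$temperature * log(c_i)
}

#' Hard-sphere excess chemical potential (BMCSL)
#'
#' Composition derivative of the BMCSL excess free-energy density. Reduces
#' to the one-component Carnahan-Starling excess chemical potential when all
#' diameters are equal.
#' @inheritParams ideal_mu
#' @return kcal/mol.
#' @export
hs_mu <- function(state, species) {
  i <- .species_index(state, species)
  rho <- state$concentrations * kpore_constants$molar_to_A3
  sigma <- state$species$hydrated_diameter
  kpore_constants$kB * state$temperature *
    density_gradient(function(r) bmcsl_f(r, sigma), rho, i)
}

#' Electrostatic excess chemical potential (MSA)
#'
#' Composition derivative of the energy-route MSA excess free-energy
#' density, with the screening parameter re-solved at each perturbed
#' composition.
#' @inheritParams ideal_mu
#' @return kcal/mol.
#' @export
msa_mu <- function(state, species) {
  i <- .species_index(state, species)
  rho <- state$concentrations * kpore_constants$molar_to_A3
  sigma <- state$species$hydrated_diameter
  z <- state$species$valence
  lB <- bjerrum_length(state)
  kpore_constants$kB * state$temperature *
    density_gradient(function(r) msa_f(r, sigma, z, lB), rho, i)
}

#' Full chemical potential of a species
#'
#' Sum of the ideal term and the excess terms selected by `model_flags`.
#' @inheritParams ideal_mu
#' @param model_flags named logical vector with elements `ideal`, `hs`,
#'   `msa`.
#' @return kcal/mol.
#' @export
chemical_potential <- function(state, species,
                               model_flags = c(ideal = TRUE, hs = TRUE, msa = TRUE)) {
  mu <- 0
  if (isTRUE(model_flags[["ideal"]])) mu <- mu + ideal_mu(state, species)
  if (isTRUE(model_flags[["hs"]]))    mu <- mu + hs_mu(state, species)
  if (isTRUE(model_flags[["msa"]]))   mu <- mu + msa_mu(state, species)
  mu
}

#' Free energy of a reservoir
#'
#' Euler-convention Gibbs free energy G = sum_i n_i mu_i over the species
#' present (default route). `route = "density"` instead integrates the
#' free-energy densities directly (ideal density sum + excess densities from
#' the charging-derived expressions), a Helmholtz-like cross-check that
#' differs from the Euler sum by the excess-pressure term.
#'
#' @param state a `solution_state`.
#' @param volume reservoir volume in litres.
#' @param model_flags named logical vector (`ideal`, `hs`, `msa`).
#' @param route `"euler"` or `"density"`.
#' @return free energy in kcal (per reservoir).
#' @export
reservoir_free_energy <- function(state, volume = 1,
                                  model_flags = c(ideal = TRUE, hs = TRUE, msa = TRUE),
                                  route = c("euler", "density")) {
  route <- match.arg(route)
  conc <- state$concentrations
  kT <- kpore_constants$kB * state$temperature
  present <- names(conc)[conc > 0]
  if (route == "euler") {
    g <- sum(vapply(present, function(s)
      conc[[s]] * chemical_potential(state, s, model_flags), numeric(1)))
    return(volume * g)
  }
  rho <- conc * kpore_constants$molar_to_A3
  sigma <- state$species$hydrated_diameter
  z <- state$species$valence
  f <- 0
  if (isTRUE(model_flags[["ideal"]]))
    f <- f + sum(ifelse(conc > 0, conc * (log(conc) - 1), 0))
  ex <- 0
  if (isTRUE(model_flags[["hs"]]))  ex <- ex + bmcsl_f(rho, sigma)
  if (isTRUE(model_flags[["msa"]])) ex <- ex + msa_f(rho, sigma, z, bjerrum_length(state))
  volume * kT * (f + ex / kpore_constants$molar_to_A3)
}
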