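# Ionic power generation: current-voltage intercept analysis, GHK reversal
# potentials, the dual-ion Coulomb energy and per-pore to areal power
# scaling. Sign convention: positive current is cation flux from the KCl to
# the NaCl reservoir.

#' Fit a linear current-voltage response
#'
#' Least-squares line through (voltage, current) samples. The current-axis
#' intercept is the net diffusive current I_diff; the voltage-axis intercept
#' is the reversal potential U_diff = -I_diff / conductance.
#'
#' @param data data.frame with columns `voltage_mV`, `current_pA`.
#' @return list with `conductance_nS` (pA/mV = nS), `I_diff_pA`,
#'   `U_diff_mV`, standard errors, and the `lm` fit.
#' @export
fit_iv <- function(data) {
  stopifnot(all(c("voltage_mV", "current_pA") %in% names(data)))
  if (length(unique(data$voltage_mV)) < 3)
    stop("need at least 3 distinct voltages")
  fit <- stats::lm(current_pA ~ voltage_mV, data = data)
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  g <- unname(cf["voltage_mV"]); i0 <- unname(cf["(Intercept)"])
  if (abs(g) < .Machine$double.eps) stop("zero slope: U_diff undefined")
  list(conductance_nS = g, I_diff_pA = i0, U_diff_mV = -i0 / g,
       se = c(conductance = unname(se["voltage_mV"]),
              I_diff = unname(se["(Intercept)"])),
       fit = fit)
}

#' Goldman-Hodgkin-Katz reversal potential
#'
#' Standard GHK voltage for monovalent ions with caller-supplied relative
#' permeabilities:
#'   U = (RT/F) ln((sum_cat P c_right + sum_an P c_left) /
#'                 (sum_cat P c_left + sum_an P c_right)),
#' reported as the potential of the left side relative to the right. With a
#' single permeant cation it reduces to the Nernst equation. Concentrations
#' may optionally be replaced by activities via `activity_coefficients`
#' (e.g. computed with [chemical_potential()]).
#'
#' @param permeabilities named vector of relative permeabilities.
#' @param valences named vector of +1/-1 valences for the same species.
#' @param conc_left,conc_right named concentration vectors, mol/L.
#' @param temperature K.
#' @param activity_coefficients optional named list with elements `left`,
#'   `right` (named vectors) multiplying the concentrations.
#' @return reversal potential in mV.
#' @export
ghk_reversal <- function(permeabilities, valences, conc_left, conc_right,
                         temperature = 300, activity_coefficients = NULL) {
  sp <- names(permeabilities)
  stopifnot(!is.null(sp), all(sp %in% names(valences)),
            all(abs(valences[sp]) == 1))
  if (all(permeabilities == 0)) stop("at least one permeability must be non-zero")
  getc <- function(conc, side) {
    x <- stats::setNames(numeric(length(sp)), sp)
    x[intersect(sp, names(conc))] <- conc[intersect(sp, names(conc))]
    if (!is.null(activity_coefficients))
      x <- x * activity_coefficients[[side]][sp]
    x
  }
  cl <- getc(conc_left, "left"); cr <- getc(conc_right, "right")
  cat_ <- valences[sp] > 0
  num <- sum(permeabilities[cat_] * cr[cat_]) + sum(permeabilities[!cat_] * cl[!cat_])
  den <- sum(permeabilities[cat_] * cl[cat_]) + sum(permeabilities[!cat_] * cr[!cat_])
  if (num <= 0 || den <= 0) stop("GHK numerator/denominator must be positive")
  rt_over_f_mV(temperature) * log(num / den)
}

#' Coulomb interaction energy of two point charges
#'
#' 332.0637 z1 z2 / (eps_r r) kcal/mol. Two potassium ions at their 3.9 A
#' dual-occupancy separation in vacuum repel by ~85 kcal/mol.
#'
#' @param valence1,valence2 signed charges in units of e.
#' @param separation distance in Angstrom, > 0.
#' @param relative_permittivity medium dielectric constant (1 = vacuum).
#' @return energy in kcal/mol.
#' @examples
#' coulomb_energy(1, 1, 3.9)  # ~85 kcal/mol
#' @export
coulomb_energy <- function(valence1, valence2, separation,
                           relative_permittivity = 1) {
  if (separation <= 0) stop("separation must be > 0")
  kpore_constants$coulomb * valence1 * valence2 /
    (relative_permittivity * separation)
}

#' Pore density of a membrane with one pore per square patch
#'
#' @param patch_edge_nm edge length of the patch in nm (10 nm gives 1e16
#'   pores/m^2).
#' @return pores per m^2.
#' @export
pore_density_from_pitch <- function(patch_edge_nm) {
  if (patch_edge_nm <= 0) stop("patch edge must be > 0")
  1 / (patch_edge_nm * 1e-9)^2
}

#' Areal power density
#'
#' @param single_pore_power_W power per pore in W.
#' @param pore_density_m2 pores per m^2.
#' @return W/m^2.
#' @export
power_density <- function(single_pore_power_W, pore_density_m2) {
  stopifnot(single_pore_power_W >= 0, pore_density_m2 >= 0)
  single_pore_power_W * pore_density_m2
}

#' Maximum extractable power of a linear I-V source
#'
#' |I_diff * U_diff| / 4, the maximum-power-transfer operating point of a
#' linear source; an explicit operating point (I, U) may be supplied
#' instead.
#'
#' @param I_diff_pA diffusive current, pA.
#' @param U_diff_mV reversal potential, mV.
#' @param operating_point optional `c(I_pA, U_mV)` to use as-is.
#' @return power in W.
#' @export
single_pore_power <- function(I_diff_pA, U_diff_mV, operating_point = NULL) {
  if (!is.null(operating_point))
    return(abs(operating_point[1] * 1e-12 * operating_point[2] * 1e-3))
  abs(I_diff_pA * 1e-12 * U_diff_mV * 1e-3) / 4
}

#' Membrane porosity
#'
#' Fraction of membrane area occupied by pores.
#' @param pore_area_A2 open area per pore, Angstrom^2.
#' @param pore_density_m2 pores per m^2.
#' @return dimensionless fraction; a value > 1 triggers an error flag.
#' @export
porosity <- function(pore_area_A2, pore_density_m2) {
  stopifnot(pore_area_A2 >= 0, pore_density_m2 >= 0)
  p <- pore_area_A2 * 1e-20 * pore_density_m2
  if (p > 1) warning("porosity exceeds 1: pore area and density are inconsistent")
  p
}

#' Read / write I-V samples as CSV
#'
#' Columns `voltage_mV,current_pA`.
#' @param path CSV path.
#' @rdname iv_io
#' @export
read_iv <- function(path) utils::read.csv(path)

#' @param data I-V data.frame.
#' @rdname iv_io
#' @export
write_iv <- function(data, path) {
  utils::write.csv(data[, c("voltage_mV", "current_pA")], path, row.names = FALSE)
  invisible(path)
}
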