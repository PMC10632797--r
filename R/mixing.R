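# Salt-mixing scenarios behind potassium-permselective osmotic power
# generation. Two reservoirs of fixed volume start as 1 M KCl (left) and
# 1 M NaCl (right). Transferring dC mol of K+ with neutral-salt bookkeeping
# gives, through a potassium-permselective membrane (KPM),
#   left: (1-dC) M KCl,  right: 1 M NaCl + dC M KCl,
# and, through a non-selective membrane (free mix),
#   left: (1-dC) M KCl + dC M NaCl,  right: (1-dC) M NaCl + dC M KCl.

kpm_compositions <- function(dC) {
  list(left = c(K = 1 - dC, Cl = 1 - dC),
       right = c(K = dC, Na = 1, Cl = 1 + dC))
}

free_mix_compositions <- function(dC) {
  list(left = c(K = 1 - dC, Na = dC, Cl = 1),
       right = c(K = dC, Na = 1 - dC, Cl = 1))
}

#' Free-energy change of the mixing process
#'
#' Evaluates dG_m(dC) = G(left) + G(right) - G(initial) over a grid of
#' transferred amounts dC, for either the potassium-permselective membrane
#' ("KPM") or the non-selective "free_mix" scenario. Both reservoirs have
#' fixed volume and the compositions follow neutral-salt bookkeeping.
#'
#' @param mode `"KPM"` or `"free_mix"`.
#' @param dC_grid grid of transferred amounts in mol/L, within [0, 1).
#' @param model_flags named logical vector selecting the ideal, hard-sphere
#'   (BMCSL) and electrostatic (MSA) terms.
#' @param temperature K.
#' @param relative_permittivity solvent dielectric constant.
#' @param species an [ion_species()] table (needs K, Na, Cl).
#' @param volume_L reservoir volume in litres.
#' @param normalization `"kJ_per_mol_salt"` (kJ per mole of initial salt per
#'   reservoir, the default reporting unit) or `"kcal"` (raw kcal per
#'   reservoir pair).
#' @param route free-energy route, see [reservoir_free_energy()].
#' @return object of class `mixing_curve`: data.frame-like list with `dC`,
#'   `dG` and the run metadata.
#' @export
mixing_curve <- function(mode = c("KPM", "free_mix"),
                         dC_grid = seq(0, 0.5, by = 0.001),
                         model_flags = c(ideal = TRUE, hs = TRUE, msa = TRUE),
                         temperature = 300, relative_permittivity = 78.4,
                         species = default_species(), volume_L = 1,
                         normalization = c("kJ_per_mol_salt", "kcal"),
                         route = "euler") {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  stopifnot(all(dC_grid >= 0), all(dC_grid < 1))
  comp_fun <- if (mode == "KPM") kpm_compositions else free_mix_compositions
  G_of <- function(conc) {
    reservoir_free_energy(
      solution_state(conc, temperature, relative_permittivity, species),
      volume = volume_L, model_flags = model_flags, route = route)
  }
  g0 <- G_of(c(K = 1, Cl = 1)) + G_of(c(Na = 1, Cl = 1))
  dG <- vapply(dC_grid, function(dC) {
    if (dC == 0) return(0)
    cmp <- comp_fun(dC)
    if (any(unlist(cmp) < 0)) stop("invalid composition: negative concentration")
    G_of(cmp$left) + G_of(cmp$right) - g0
  }, numeric(1))
  # kcal per reservoir pair -> requested normalization
  scale <- switch(normalization,
    kcal = 1,
    kJ_per_mol_salt = 4.184 / (volume_L * 1))  # 1 M initial salt per reservoir
  structure(list(mode = mode, dC = dC_grid, dG = dG * scale,
                 model_flags = model_flags, temperature = temperature,
                 normalization = normalization, route = route),
            class = "mixing_curve")
}

#' @export
print.mixing_curve <- function(x, ...) {
  cat(sprintf("mixing curve (%s, %s): %d points on [%.3g, %.3g] M, min %.4g at dC = %.3g M\n",
              x$mode, x$normalization, length(x$dC), min(x$dC), max(x$dC),
              min(x$dG), x$dC[which.min(x$dG)]))
  invisible(x)
}

#' Terminus of the spontaneous transfer branch
#'
#' Location dC0 of the interior minimum of a mixing curve; the grid argmin
#' refined by a local quadratic fit through the three bracketing points.
#'
#' @param curve a `mixing_curve`.
#' @return dC0 in mol/L.
#' @export
spontaneous_terminus <- function(curve) {
  i <- which.min(curve$dG)
  if (i == 1 || i == length(curve$dG))
    stop("monotone curve: no interior minimum")
  x <- curve$dC[(i - 1):(i + 1)]
  y <- curve$dG[(i - 1):(i + 1)]
  cf <- stats::coef(stats::lm(y ~ x + I(x^2)))
  if (!is.finite(cf[3]) || cf[3] <= 0) return(curve$dC[i])
  unname(-cf[2] / (2 * cf[3]))
}

# linear interpolation of a curve at dC
curve_at <- function(curve, dC) {
  stats::approx(curve$dC, curve$dG, xout = dC)$y
}

#' Energy conversion efficiency of the permselective mixing process
#'
#' At a transferred amount dC on the spontaneous branch, ON is the magnitude
#' of the KPM-curve free-energy change (extractable work with a
#' potassium-permselective membrane) and OP that of the free-mix curve (work
#' lost in unrestrained mixing); the conversion efficiency is eta = ON/OP.
#' The ratio is invariant under any common rescaling of the energy axis.
#'
#' @param curve_KPM,curve_free `mixing_curve` objects for the two modes on
#'   compatible grids and the same normalization.
#' @param dC evaluation point, mol/L; must lie on the spontaneous branch
#'   (dG_KPM(dC) < 0).
#' @return list with `ON`, `OP` (in the curves' normalization) and `eta`.
#' @export
efficiency <- function(curve_KPM, curve_free, dC) {
  stopifnot(identical(curve_KPM$normalization, curve_free$normalization))
  gk <- curve_at(curve_KPM, dC)
  gf <- curve_at(curve_free, dC)
  if (!is.finite(gk) || !is.finite(gf)) stop("dC outside the curve grid")
  if (gk >= 0) stop("dC beyond the spontaneous branch (dG_KPM >= 0)")
  list(ON = abs(gk), OP = abs(gf), eta = abs(gk) / abs(gf))
}

#' Write a mixing curve as CSV / summarize as JSON-ready list
#'
#' @param curve a `mixing_curve`.
#' @param path output CSV path (`dC_M,dG_m`).
#' @export
write_mixing_curve <- function(curve, path) {
  utils::write.csv(data.frame(dC_M = curve$dC, dG_m = curve$dG),
                   path, row.names = FALSE)
  invisible(path)
}
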