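# Transition-state-theory permeation kinetics: attempt period from the
# velocity autocorrelation function and k = tau^-1 exp(-beta dG).

#' Create a velocity time series
#'
#' @param values velocity samples (any consistent unit; only the time of the
#'   VACF zero crossings matters).
#' @param timestep_ps sampling interval in ps.
#' @return object of class `velocity_series`.
#' @export
velocity_series <- function(values, timestep_ps) {
  stopifnot(is.numeric(values), length(values) >= 10,
            is.numeric(timestep_ps), timestep_ps > 0)
  structure(list(values = as.numeric(values), timestep_ps = timestep_ps),
            class = "velocity_series")
}

#' Read / write a velocity series
#'
#' One column of samples; the header comment line carries the timestep, e.g.
#' `# timestep_ps 0.002`.
#' @param path file path.
#' @rdname velocity_io
#' @export
read_velocity_series <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*timestep_ps", lines, value = TRUE)
  if (length(hdr) == 0) stop("missing '# timestep_ps' header")
  dt <- as.numeric(sub("^#\\s*timestep_ps\\s+", "", hdr[1]))
  vals <- as.numeric(lines[!startsWith(lines, "#")])
  velocity_series(vals[!is.na(vals)], dt)
}

#' @param series a `velocity_series`.
#' @rdname velocity_io
#' @export
write_velocity_series <- function(series, path) {
  writeLines(c(sprintf("# timestep_ps %.10g", series$timestep_ps),
               format(series$values, digits = 10)), path)
  invisible(path)
}

# normalized velocity autocorrelation up to max_lag samples
vacf <- function(values, max_lag) {
  n <- length(values)
  max_lag <- min(max_lag, n - 2)
  c0 <- mean(values^2)
  vapply(0:max_lag, function(k) {
    mean(values[1:(n - k)] * values[(1 + k):n]) / c0
  }, numeric(1))
}

#' Attempt period from the velocity autocorrelation function
#'
#' The attempt period tau of the adsorbed ion is estimated as the time of the
#' second zero of the normalized VACF (three quarters of the vibration period
#' for a pure cosine). Zeros are located by sign change with linear
#' interpolation. The VACF must rebound below `-min_excursion` between the
#' two zeros; a series without that oscillatory structure (e.g. white noise)
#' is rejected.
#'
#' @param series a `velocity_series`.
#' @param max_lag_ps how far to evaluate the VACF (default: a third of the
#'   series duration).
#' @param min_excursion required depth of the negative VACF lobe (default
#'   0.1).
#' @return tau in ps.
#' @export
attempt_period_from_vacf <- function(series, max_lag_ps = NULL,
                                     min_excursion = 0.1) {
  dt <- series$timestep_ps
  if (is.null(max_lag_ps)) max_lag_ps <- length(series$values) * dt / 3
  cc <- vacf(series$values, round(max_lag_ps / dt))
  sgn <- sign(cc)
  cross <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  if (length(cross) < 2)
    stop("no oscillatory structure: fewer than two VACF zero crossings")
  z1 <- cross[1]; z2 <- cross[2]
  if (min(cc[z1:z2]) > -min_excursion)
    stop("no oscillatory structure: VACF lacks a negative lobe")
  # crossing between lags (k-1) and k at index k in cc (lag k-1 zero-based)
  interp <- function(k) {
    lag <- k - 1                       # zero-based lag of cc[k]
    (lag + cc[k] / (cc[k] - cc[k + 1])) * dt
  }
  interp(z2)
}

#' Transition-state-theory permeation rate
#'
#' k = tau^-1 exp(-dG / (kB T)) with kB = 0.0019872 kcal/(mol K).
#'
#' @param dG free energy barrier, kcal/mol.
#' @param tau_ps attempt period, ps.
#' @param temperature temperature in K (default 300).
#' @return rate in 1/s.
#' @examples
#' permeation_rate(0, 1)  # 1e12
#' @export
permeation_rate <- function(dG, tau_ps, temperature = 300) {
  stopifnot(tau_ps > 0, temperature > 0)
  1e12 / tau_ps * exp(-dG / (kpore_constants$kB * temperature))
}

#' K+/Na+ selectivity ratio
#'
#' Ratio of the permeation rates of the two ions.
#' @param k_K,k_Na permeation rates in 1/s, both > 0.
#' @export
selectivity_ratio <- function(k_K, k_Na) {
  if (k_K <= 0 || k_Na <= 0) stop("rates must be positive")
  k_K / k_Na
}
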