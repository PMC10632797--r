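# Linear decomposition of the hopping barrier into ion-water, carbonyl and
# ion-membrane contributions:
#   dG = a * dN_water + b * dN_carbonyl + c
# where dN_water is the change in hydration number across the hop, dN_carbonyl
# the change in carbonyl coordination, and c the residual membrane term
# (treated as an ion-independent constant and fitted as the intercept).

#' Fit the free-energy-barrier decomposition
#'
#' Ordinary least squares of `dG` on `(dN_water, dN_carbonyl, 1)`. The fit is
#' done per ion; a negative carbonyl coefficient means carbonyl coordination
#' assists the layer-to-layer hop (the K+ signature), a positive one opposes
#' it (the Na+ signature).
#'
#' @param samples data.frame with columns `dN_water`, `dN_carbonyl`, `dG`
#'   (kcal/mol).
#' @return object of class `barrier_decomposition` with elements
#'   `coefficients` (named: `water`, `carbonyl`, `membrane`), `std_errors`,
#'   `residuals` and the underlying `lm` fit.
#' @export
fit_decomposition <- function(samples) {
  req <- c("dN_water", "dN_carbonyl", "dG")
  if (!all(req %in% names(samples))) stop("samples need columns dN_water, dN_carbonyl, dG")
  if (!all(is.finite(as.matrix(samples[req])))) stop("samples must be finite")
  if (nrow(samples) < 4) stop("rank-deficient design: need at least 4 samples")
  X <- cbind(1, samples$dN_water, samples$dN_carbonyl)
  if (qr(X)$rank < 3) stop("rank-deficient design")
  fit <- stats::lm(dG ~ dN_water + dN_carbonyl, data = samples)
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  structure(list(
    coefficients = c(water = unname(cf["dN_water"]),
                     carbonyl = unname(cf["dN_carbonyl"]),
                     membrane = unname(cf["(Intercept)"])),
    std_errors = c(water = unname(se["dN_water"]),
                   carbonyl = unname(se["dN_carbonyl"]),
                   membrane = unname(se["(Intercept)"])),
    residuals = stats::residuals(fit),
    fit = fit
  ), class = "barrier_decomposition")
}

#' @export
print.barrier_decomposition <- function(x, ...) {
  cf <- x$coefficients; se <- x$std_errors
  cat(sprintf(paste0("barrier decomposition: dG = %.3f*dN_water %+.3f*dN_carbonyl %+.3f\n",
                     "  (std. errors %.3g, %.3g, %.3g; n = %d)\n"),
              cf["water"], cf["carbonyl"], cf["membrane"],
              se["water"], se["carbonyl"], se["membrane"],
              length(x$residuals)))
  invisible(x)
}

#' Predict a hopping barrier from the fitted decomposition
#'
#' @param fit a `barrier_decomposition`.
#' @param dN_water,dN_carbonyl changes in hydration number and carbonyl
#'   coordination.
#' @return predicted barrier, kcal/mol.
#' @export
predict_barrier <- function(fit, dN_water, dN_carbonyl) {
  cf <- fit$coefficients
  unname(cf["water"] * dN_water + cf["carbonyl"] * dN_carbonyl + cf["membrane"])
}

#' Read decomposition samples from CSV
#'
#' Expects columns `dN_water, dN_carbonyl, dG_kcal_mol`.
#' @param path CSV path.
#' @export
read_decomposition_samples <- function(path) {
  d <- utils::read.csv(path)
  data.frame(dN_water = d$dN_water, dN_carbonyl = d$dN_carbonyl,
             dG = d$dG_kcal_mol)
}
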