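# Potential-of-mean-force profiles: container, IO, normalization, extrema
# and the rate-determining hopping barrier.

#' Create a PMF profile
#'
#' @param coordinate strictly increasing reaction-coordinate grid (Angstrom,
#'   along the pore axis).
#' @param free_energy free energy at each grid point (kcal/mol).
#' @param reference_region optional `c(lo, hi)` interval defining the bulk
#'   zero.
#' @param annotations optional named list of marked intervals, e.g. layer
#'   positions `list(L1 = c(-0.5, 0.5), L2 = c(2.85, 3.85))`.
#' @return object of class `pmf_profile`.
#' @export
pmf_profile <- function(coordinate, free_energy, reference_region = NULL,
                        annotations = NULL) {
  stopifnot(length(coordinate) == length(free_energy), length(coordinate) >= 3)
  if (any(diff(coordinate) <= 0)) stop("coordinate grid must be strictly increasing")
  if (!all(is.finite(free_energy))) stop("free energy must be finite")
  structure(list(coordinate = as.numeric(coordinate),
                 free_energy = as.numeric(free_energy),
                 reference_region = reference_region,
                 annotations = annotations),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF profile: %d points on [%.2f, %.2f] A, range [%.2f, %.2f] kcal/mol\n",
              length(x$coordinate), min(x$coordinate), max(x$coordinate),
              min(x$free_energy), max(x$free_energy)))
  invisible(x)
}

#' Read / write a PMF profile as two-column TSV
#'
#' The on-disk format is `coordinate_A<TAB>pmf_kcal_mol` with `#` comment
#' lines.
#' @param path file path.
#' @rdname pmf_io
#' @export
read_pmf <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  pmf_profile(d[[1]], d[[2]])
}

#' @param profile a `pmf_profile`.
#' @rdname pmf_io
#' @export
write_pmf <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# PMF profile (reaction coordinate in A, free energy in kcal/mol)", con)
  utils::write.table(
    data.frame(coordinate_A = profile$coordinate,
               pmf_kcal_mol = profile$free_energy),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize a PMF to a bulk reference region
#'
#' Shifts the profile so the mean free energy over the reference region is
#' zero.
#' @param profile a `pmf_profile`.
#' @param reference_region `c(lo, hi)`; defaults to the profile's own region.
#' @export
normalize_pmf <- function(profile, reference_region = profile$reference_region) {
  if (is.null(reference_region)) stop("no reference region given")
  sel <- profile$coordinate >= reference_region[1] &
         profile$coordinate <= reference_region[2]
  if (!any(sel)) stop("reference region does not overlap the coordinate grid")
  out <- profile
  out$free_energy <- profile$free_energy - mean(profile$free_energy[sel])
  out$reference_region <- reference_region
  out
}

# centred moving average; window is forced odd
smooth_ma <- function(y, window) {
  if (window <= 1) return(y)
  w <- 2 * (window %/% 2) + 1
  half <- w %/% 2
  n <- length(y)
  vapply(seq_len(n), function(i) {
    j <- max(1, i - half):min(n, i + half)
    mean(y[j])
  }, numeric(1))
}

#' Locate minima and maxima of a PMF
#'
#' Smooths with a centred moving average (adaptive-biasing-force profiles are
#' noisy) and reports interior extrema as alternating minima and maxima.
#'
#' @param profile a `pmf_profile`.
#' @param smoothing_window moving-average width in grid points (default 3;
#'   1 disables smoothing).
#' @param min_prominence drop adjacent min/max pairs closer in free energy
#'   than this (kcal/mol); 0 keeps every sign change. Noise-induced ripples
#'   have small prominence, physical wells and saddles do not.
#' @return data.frame with columns `position`, `value`, `kind` (`"min"` or
#'   `"max"`).
#' @export
locate_extrema <- function(profile, smoothing_window = 3, min_prominence = 0) {
  y <- smooth_ma(profile$free_energy, smoothing_window)
  x <- profile$coordinate
  s <- sign(diff(y))
  # carry the previous non-zero slope through flat stretches
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) != 0 & s[-length(s)] != 0) + 1
  if (length(idx) == 0) stop("no interior extremum found")
  ext <- data.frame(
    position = x[idx],
    value = y[idx],
    kind = ifelse(s[idx - 1] < 0, "min", "max"),
    stringsAsFactors = FALSE
  )
  # persistence pruning: remove shallow adjacent min/max pairs (alternation
  # is preserved) and edge ripples that barely depart from the end values
  if (min_prominence > 0) {
    repeat {
      changed <- FALSE
      while (nrow(ext) >= 2) {
        d <- abs(diff(ext$value))
        i <- which.min(d)
        if (d[i] >= min_prominence) break
        ext <- ext[-c(i, i + 1), , drop = FALSE]
        changed <- TRUE
      }
      if (nrow(ext) >= 1 && abs(ext$value[1] - y[1]) < min_prominence) {
        ext <- ext[-1, , drop = FALSE]; changed <- TRUE
      }
      if (nrow(ext) >= 1 &&
          abs(ext$value[nrow(ext)] - y[length(y)]) < min_prominence) {
        ext <- ext[-nrow(ext), , drop = FALSE]; changed <- TRUE
      }
      if (!changed) break
    }
  }
  if (nrow(ext) == 0) stop("no interior extremum found")
  rownames(ext) <- NULL
  ext
}

#' Rate-determining hopping barrier between the two layers
#'
#' The rate-determining step of permeation is the hop from the binding site
#' at the first layer (L1) to that at the second (L2); the barrier is the
#' free energy at the highest point between the two layer minima, minus the
#' L1 minimum.
#'
#' @param profile a `pmf_profile`.
#' @param layer_annotations named list with intervals `L1` and `L2`
#'   (`c(lo, hi)` in Angstrom); defaults to the profile's annotations.
#' @param smoothing_window passed to the internal smoothing (default 1: use
#'   the profile as given).
#' @return barrier height in kcal/mol.
#' @export
rate_determining_barrier <- function(profile,
                                     layer_annotations = profile$annotations,
                                     smoothing_window = 1) {
  if (is.null(layer_annotations$L1) || is.null(layer_annotations$L2))
    stop("both layer intervals (L1, L2) must be annotated")
  x <- profile$coordinate
  y <- smooth_ma(profile$free_energy, smoothing_window)
  pick_min <- function(iv, name) {
    sel <- which(x >= iv[1] & x <= iv[2])
    if (length(sel) == 0) stop(sprintf("missing minimum: interval %s off grid", name))
    sel[which.min(y[sel])]
  }
  i1 <- pick_min(layer_annotations$L1, "L1")
  i2 <- pick_min(layer_annotations$L2, "L2")
  between <- min(i1, i2):max(i1, i2)
  max(y[between]) - y[i1]
}
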