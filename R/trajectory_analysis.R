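# Operators over tagged-particle trajectories: site occupancy, permeation
# events, hydration numbers, ion-water-ion triplet classification, water
# dipole orientation and switching frequency.

ion_rows <- function(traj) which(traj$atoms$role %in% c("ionK", "ionNa"))

# minimum-image displacement component-wise
min_image <- function(d, box, periodic) {
  for (k in 1:3) if (periodic[k]) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Per-frame pore-site occupancy
#'
#' An ion occupies site P1/P2 (the binding site at layer 1/2) when its axial
#' distance to the layer plane is within `axial_tolerance` and its radial
#' distance to the pore axis within `radial_cutoff`; when several ions
#' qualify the axially nearest wins, and an ion is assigned to at most one
#' site.
#'
#' @param traj an `md_trajectory`.
#' @param axial_tolerance Angstrom (default 1.0).
#' @param radial_cutoff Angstrom (default 3.0).
#' @return integer matrix `n_frames x 2` (columns `P1`, `P2`) of occupying
#'   ion ids, NA when empty.
#' @export
assign_site_occupancy <- function(traj, axial_tolerance = 1.0,
                                  radial_cutoff = 3.0) {
  ions <- ion_rows(traj)
  if (length(ions) == 0) stop("no tagged ions in trajectory")
  nf <- n_frames(traj)
  occ <- matrix(NA_integer_, nf, 2, dimnames = list(NULL, c("P1", "P2")))
  ids <- traj$atoms$id[ions]
  for (s in 1:2) {
    zs <- traj$layer_z[s]
    # axial and radial distances: ions x frames
    dz <- abs(traj$coords[ions, 3, , drop = FALSE] - zs)
    rad2 <- traj$coords[ions, 1, , drop = FALSE]^2 +
            traj$coords[ions, 2, , drop = FALSE]^2
    ok <- dz[, 1, ] <= axial_tolerance & rad2[, 1, ] <= radial_cutoff^2
    dzm <- dz[, 1, ]
    if (length(ions) == 1) { ok <- matrix(ok, 1); dzm <- matrix(dzm, 1) }
    dzm[!ok] <- Inf
    best <- apply(dzm, 2, which.min)
    hit <- apply(dzm, 2, min) < Inf
    occ[hit, s] <- ids[best[hit]]
  }
  # an ion bound to both planes (mid-gap) goes to the nearer one
  both <- !is.na(occ[, 1]) & !is.na(occ[, 2]) & occ[, 1] == occ[, 2]
  if (any(both)) {
    for (f in which(both)) {
      i <- ions[match(occ[f, 1], traj$atoms$id[ions])]
      z <- traj$coords[i, 3, f]
      nearer <- which.min(abs(traj$layer_z - z))
      occ[f, -nearer] <- NA_integer_
    }
  }
  occ
}

#' Detect permeation events
#'
#' An event is a continuous passage of an ion from beyond `entry_margin`
#' outside one layer plane to beyond `exit_margin` outside the other,
#' crossing both planes; the margins act as hysteresis so shuttling in and
#' out of the pore mouth (capture followed by retreat) is not counted.
#' Periodic wrap-around along the pore axis is handled.
#'
#' @param traj an `md_trajectory`.
#' @param entry_margin,exit_margin Angstrom beyond the layer planes.
#' @return data.frame with columns `ion_id`, `start_frame`, `end_frame`,
#'   `direction` (+1: from below layer 1 to above layer 2).
#' @export
detect_permeation_events <- function(traj, entry_margin = 2, exit_margin = 2) {
  lo_th <- traj$layer_z[1] - entry_margin
  hi_th <- traj$layer_z[2] + exit_margin
  Lz <- traj$box[3]
  events <- list()
  for (i in ion_rows(traj)) {
    z <- traj$coords[i, 3, ]
    region <- function(zv) if (zv < lo_th) "low" else if (zv > hi_th) "high" else "mid"
    state <- region(z[1])
    entered <- NA_integer_
    for (f in 2:length(z)) {
      wrap <- traj$periodic[3] && abs(z[f] - z[f - 1]) > Lz / 2
      r <- region(z[f])
      if (wrap) { state <- r; entered <- NA_integer_; next }
      if (r == "mid") {
        if (state %in% c("low", "high") && is.na(entered)) entered <- f
        next
      }
      if (r != state) {
        if (state %in% c("low", "high")) {
          events[[length(events) + 1]] <- data.frame(
            ion_id = traj$atoms$id[i],
            start_frame = if (is.na(entered)) f else entered,
            end_frame = f,
            direction = if (r == "high") 1L else -1L)
        }
        state <- r
      }
      entered <- NA_integer_
    }
  }
  if (length(events) == 0)
    return(data.frame(ion_id = integer(), start_frame = integer(),
                      end_frame = integer(), direction = integer()))
  do.call(rbind, events)
}

#' Hydration number of a tagged ion
#'
#' Counts water oxygens within `cutoff` of the ion per frame
#' (minimum-image distances). The default 3.5 A is the first minimum of the
#' K+-water oxygen radial distribution in common water models; use ~3.2 A
#' for Na+.
#'
#' @param traj an `md_trajectory`.
#' @param ion_id id of the tagged ion.
#' @param cutoff Angstrom.
#' @return list with `per_frame` (integer vector) and `mean`.
#' @export
hydration_number <- function(traj, ion_id, cutoff = 3.5) {
  i <- which(traj$atoms$id == ion_id)
  if (length(i) != 1) stop("unknown ion id")
  wo <- which(traj$atoms$role == "waterO")
  if (length(wo) == 0) stop("no tagged water oxygens in trajectory")
  nf <- n_frames(traj)
  counts <- vapply(seq_len(nf), function(f) {
    d <- sweep(traj$coords[wo, , f, drop = FALSE][, , 1, drop = TRUE], 2,
               traj$coords[i, , f])
    if (length(wo) == 1) d <- matrix(d, 1)
    d <- min_image(d, traj$box, traj$periodic)
    sum(rowSums(d^2) <= cutoff^2)
  }, integer(1))
  list(per_frame = counts, mean = mean(counts))
}

# waters bridging the two site-bound ions in a given frame: oxygens strictly
# between the layer planes and within radial_cutoff of the inter-ion axis
bridging_waters <- function(traj, f, id1, id2, radial_cutoff) {
  wo <- which(traj$atoms$role == "waterO")
  i1 <- which(traj$atoms$id == id1); i2 <- which(traj$atoms$id == id2)
  p1 <- traj$coords[i1, , f]; p2 <- traj$coords[i2, , f]
  axis <- p2 - p1; L <- sqrt(sum(axis^2)); u <- axis / L
  keep <- logical(length(wo))
  for (k in seq_along(wo)) {
    w <- traj$coords[wo[k], , f]
    if (w[3] <= min(traj$layer_z) || w[3] >= max(traj$layer_z)) next
    t_ <- sum((w - p1) * u)
    perp <- (w - p1) - t_ * u
    keep[k] <- sqrt(sum(perp^2)) <= radial_cutoff
  }
  traj$atoms$mol[wo[keep]]
}

#' Classify ion-water-ion triplet episodes
#'
#' A triplet episode is a maximal run of frames with both pore sites
#' occupied. Each episode is labelled by the modal number of interlayer
#' water molecules bridging the two ions (1 or 2); its lifetime is the
#' episode duration. Episodes whose modal bridge count is 0 (or > 2) are
#' excluded and reported in `n_excluded`.
#'
#' @param traj an `md_trajectory`.
#' @param site_map occupancy matrix from [assign_site_occupancy()];
#'   computed if NULL.
#' @param radial_cutoff cylinder radius about the inter-ion axis, Angstrom.
#' @return list with `events` (data.frame: `ion1`, `ion2`, `n_waters`,
#'   `start_frame`, `end_frame`, `lifetime_ps`) and `summary` (fractions
#'   and mean lifetimes by bridge count, plus `n_excluded`).
#' @export
classify_triplets <- function(traj, site_map = NULL, radial_cutoff = 3.0) {
  if (is.null(site_map)) site_map <- assign_site_occupancy(traj)
  dual <- !is.na(site_map[, 1]) & !is.na(site_map[, 2])
  runs <- rle(dual)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ev <- list(); n_excluded <- 0L
  for (r in which(runs$values)) {
    f0 <- starts[r]; f1 <- ends[r]
    id1 <- site_map[f0, 1]; id2 <- site_map[f0, 2]
    # modal bridge count over (up to) 32 probe frames spread over the episode
    probe <- unique(round(seq(f0, f1, length.out = min(32, f1 - f0 + 1))))
    counts <- vapply(probe, function(f)
      length(bridging_waters(traj, f, id1, id2, radial_cutoff)), integer(1))
    n_mode <- as.integer(names(which.max(table(counts))))
    if (n_mode < 1 || n_mode > 2) { n_excluded <- n_excluded + 1L; next }
    ev[[length(ev) + 1]] <- data.frame(
      ion1 = id1, ion2 = id2, n_waters = n_mode,
      start_frame = f0, end_frame = f1,
      lifetime_ps = (f1 - f0 + 1) * traj$timestep_ps)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(ion1 = integer(), ion2 = integer(), n_waters = integer(),
               start_frame = integer(), end_frame = integer(),
               lifetime_ps = numeric())
  frac <- function(n) if (nrow(events)) mean(events$n_waters == n) else NA_real_
  mlt <- function(n) {
    x <- events$lifetime_ps[events$n_waters == n]
    if (length(x)) mean(x) else NA_real_
  }
  list(events = events,
       summary = list(fraction_n1 = frac(1), fraction_n2 = frac(2),
                      mean_lifetime_n1 = mlt(1), mean_lifetime_n2 = mlt(2),
                      n_episodes = nrow(events), n_excluded = n_excluded))
}

#' Water dipole orientation relative to the inter-ion axis
#'
#' For one water molecule over a frame range, computes the angle theta
#' between the water dipole (from the oxygen through the H-H midpoint) and
#' the axis from the first to the second site-bound ion.
#'
#' @param traj an `md_trajectory`.
#' @param water_mol water molecule id.
#' @param ion_ids `c(id1, id2)`; the axis points from id1 to id2.
#' @param frames frame indices (default all).
#' @return object of class `orientation_series`: list with `time_ps` and
#'   `theta_deg` in [0, 180].
#' @export
dipole_orientation <- function(traj, water_mol, ion_ids, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  o <- which(traj$atoms$role == "waterO" & traj$atoms$mol == water_mol)
  h <- which(traj$atoms$role == "waterH" & traj$atoms$mol == water_mol)
  if (length(o) != 1 || length(h) != 2) stop("water molecule must have one O and two H")
  i1 <- which(traj$atoms$id == ion_ids[1]); i2 <- which(traj$atoms$id == ion_ids[2])
  stopifnot(length(i1) == 1, length(i2) == 1)
  theta <- vapply(frames, function(f) {
    dip <- (traj$coords[h[1], , f] + traj$coords[h[2], , f]) / 2 -
           traj$coords[o, , f]
    nd <- sqrt(sum(dip^2))
    if (nd < 1e-8) stop("degenerate geometry: collinear H-O-H")
    ax <- traj$coords[i2, , f] - traj$coords[i1, , f]
    na <- sqrt(sum(ax^2))
    acos(max(-1, min(1, sum(dip * ax) / (nd * na)))) * 180 / pi
  }, numeric(1))
  structure(list(time_ps = traj$times[frames], theta_deg = theta,
                 timestep_ps = traj$timestep_ps),
            class = "orientation_series")
}

#' Peaks of an orientation histogram
#'
#' Histograms theta on [0, 180] and reports local maxima of the smoothed
#' counts.
#' @param series an `orientation_series` (or numeric vector of angles).
#' @param bin_width degrees.
#' @param smoothing_window bins for the centred moving average.
#' @return numeric vector of peak locations in degrees.
#' @export
orientation_peaks <- function(series, bin_width = 5, smoothing_window = 3) {
  theta <- if (inherits(series, "orientation_series")) series$theta_deg else series
  breaks <- seq(0, 180, by = bin_width)
  hh <- graphics::hist(theta, breaks = breaks, plot = FALSE)
  y <- smooth_ma(hh$counts, smoothing_window)
  n <- length(y)
  peaks <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf) & y > max(y) * 0.2)
  hh$mids[peaks]
}

#' Switching frequency of a two-state orientation series
#'
#' Frames are labelled state A when theta < 90 - threshold and state B when
#' theta > 90 + threshold (ambiguous frames keep the previous state); runs
#' shorter than `debounce` frames are merged into their predecessor. The
#' frequency is transitions / (2 * duration), i.e. full switching cycles
#' per unit time.
#'
#' @param series an `orientation_series`.
#' @param threshold degrees around 90 (default 15).
#' @param debounce minimum run length in frames (default 2; use 0 or 1 to
#'   disable).
#' @return frequency in GHz.
#' @export
switching_frequency <- function(series, threshold = 15, debounce = 2) {
  stopifnot(length(series$theta_deg) >= 10)
  th <- series$theta_deg
  lab <- ifelse(th < 90 - threshold, 1L, ifelse(th > 90 + threshold, 2L, 0L))
  for (i in seq_along(lab)) if (lab[i] == 0L && i > 1) lab[i] <- lab[i - 1]
  lab <- lab[lab != 0L]
  if (length(lab) < 2) stop("all-ambiguous orientation series")
  if (debounce > 1) {
    r <- rle(lab)
    keep <- r$lengths >= debounce
    if (!any(keep)) stop("all-ambiguous orientation series")
    v <- r$values[keep]
    v <- v[c(TRUE, diff(v) != 0)]
    transitions <- length(v) - 1
  } else {
    transitions <- sum(diff(lab) != 0)
  }
  duration_ps <- length(series$theta_deg) * series$timestep_ps
  transitions / (2 * duration_ps) * 1000  # 1/ps -> GHz
}
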