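# Seeded generators for every input the pipeline consumes. Each generator
# is deterministic given its seed and attaches its full parameterization as
# the "generator_spec" attribute (the provenance contract); identical specs
# give bit-identical output.

generator_spec <- function(kind, params, seed) {
  list(kind = kind, params = params, seed = seed)
}

#' Write a generator's provenance metadata as JSON
#'
#' @param obj an object produced by one of the `gen_*` generators.
#' @param path output JSON path.
#' @export
write_generator_metadata <- function(obj, path) {
  spec <- attr(obj, "generator_spec")
  if (is.null(spec)) stop("object carries no generator_spec")
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Generate a multi-well PMF profile
#'
#' Builds a free-energy profile that attains prescribed well values at the
#' well positions and saddle values between consecutive wells
#' (saddle_j = well_j + barrier_heights[j]), decaying to the bulk zero away
#' from the pore. The curve is a monotone Hermite spline between the
#' well/saddle/bulk anchors, so the anchors are the exact extrema (to
#' within grid sampling, well below 0.01 kcal/mol) and no spurious extrema
#' appear. The default two-well geometry places the wells at the two layer
#' planes (z = 0 and 3.35 A).
#'
#' @param well_depths free energy at each well, kcal/mol (negative for
#'   binding).
#' @param well_positions well locations along the pore axis, Angstrom.
#' @param barrier_heights barrier from well j to the saddle between wells j
#'   and j+1, kcal/mol (length = wells - 1).
#' @param noise_sd Gaussian noise added per grid point, kcal/mol.
#' @param seed RNG seed.
#' @param grid_step,pad grid spacing and bulk padding beyond the outer
#'   wells, Angstrom.
#' @return a [pmf_profile()] annotated with layer intervals L1, L2 (first
#'   and last well) and a bulk reference region.
#' @export
gen_pmf <- function(well_depths, well_positions, barrier_heights,
                    noise_sd = 0, seed = 1, grid_step = 0.05, pad = 6) {
  nw <- length(well_depths)
  stopifnot(nw >= 1, length(well_positions) == nw,
            length(barrier_heights) == nw - 1,
            !is.unsorted(well_positions, strictly = TRUE))
  saddle_pos <- if (nw > 1) (well_positions[-nw] + well_positions[-1]) / 2 else numeric()
  saddle_val <- if (nw > 1) well_depths[-nw] + barrier_heights else numeric()
  if (nw > 1 && any(saddle_val <= pmax(well_depths[-nw], well_depths[-1])))
    stop("inconsistent geometry: saddles must lie above both adjacent wells")
  x0 <- min(well_positions) - pad
  x1 <- max(well_positions) + pad
  nodes <- c(x0, x0 / 2 + min(well_positions) / 2,
             well_positions, saddle_pos,
             x1 / 2 + max(well_positions) / 2, x1)
  vals <- c(0, 0, well_depths, saddle_val, 0, 0)
  ord <- order(nodes)
  nodes <- nodes[ord]; vals <- vals[ord]
  # zero-slope cubic Hermite between anchors: monotone on each interval,
  # exact extrema at the anchors
  fy <- function(xq) {
    i <- pmin(pmax(findInterval(xq, nodes), 1), length(nodes) - 1)
    t <- (xq - nodes[i]) / (nodes[i + 1] - nodes[i])
    vals[i] + (vals[i + 1] - vals[i]) * (3 * t^2 - 2 * t^3)
  }
  x <- seq(x0, x1, by = grid_step)
  y <- fy(x)
  y <- with_seed(seed, function() y + stats::rnorm(length(y), 0, noise_sd))
  ann <- list(L1 = well_positions[1] + c(-1, 1),
              L2 = well_positions[nw] + c(-1, 1))
  prof <- pmf_profile(x, y,
                      reference_region = c(min(x), min(well_positions) - pad / 2),
                      annotations = ann)
  attr(prof, "generator_spec") <- generator_spec("pmf", list(
    well_depths = well_depths, well_positions = well_positions,
    barrier_heights = barrier_heights, noise_sd = noise_sd,
    grid_step = grid_step, pad = pad), seed)
  prof
}

#' Potassium-like and sodium-like reference PMFs
#'
#' Convenience wrappers around [gen_pmf()] with the hopping geometry of the
#' twisted-carbonyl bilayer channel: for K+, wells of -6.0 (L1) and -6.4
#' (L2) kcal/mol with a 3.5 kcal/mol hop barrier; for Na+, a -6.9 kcal/mol
#' L1 well, an 8.9 kcal/mol hop barrier and a shallow L2 well.
#' @param noise_sd,seed passed to [gen_pmf()].
#' @rdname reference_pmfs
#' @export
gen_pmf_potassium <- function(noise_sd = 0, seed = 1)
  gen_pmf(c(-6.0, -6.4), c(0, 3.35), 3.5, noise_sd, seed)

#' @rdname reference_pmfs
#' @export
gen_pmf_sodium <- function(noise_sd = 0, seed = 1)
  gen_pmf(c(-6.9, -1.0), c(0, 3.35), 8.9, noise_sd, seed)

#' Generate a damped-oscillator velocity series
#'
#' v(t) = exp(-zeta w t) cos(wd t) + noise, with w = 2 pi / period and
#' wd = w sqrt(1 - zeta^2): the velocity of an ion vibrating in its binding
#' site, whose VACF second zero estimates the attempt period.
#'
#' @param period_ps vibration period T0, ps.
#' @param damping_ratio zeta in [0, 1).
#' @param n_periods series length in periods (>= 3).
#' @param timestep_ps sampling interval; must resolve the period
#'   (< period/10).
#' @param noise_sd thermal noise amplitude.
#' @param seed RNG seed.
#' @return a [velocity_series()].
#' @export
gen_oscillator_velocities <- function(period_ps, damping_ratio = 0,
                                      n_periods = 10, timestep_ps = period_ps / 100,
                                      noise_sd = 0, seed = 1) {
  if (timestep_ps >= period_ps / 10)
    stop("undersampling: timestep must be < period/10")
  stopifnot(n_periods >= 3, damping_ratio >= 0, damping_ratio < 1)
  t <- seq(0, n_periods * period_ps, by = timestep_ps)
  w <- 2 * pi / period_ps
  wd <- w * sqrt(1 - damping_ratio^2)
  v <- with_seed(seed, function()
    exp(-damping_ratio * w * t) * cos(wd * t) +
      stats::rnorm(length(t), 0, noise_sd))
  out <- velocity_series(v, timestep_ps)
  attr(out, "generator_spec") <- generator_spec("vacf", list(
    period_ps = period_ps, damping_ratio = damping_ratio,
    n_periods = n_periods, timestep_ps = timestep_ps,
    noise_sd = noise_sd), seed)
  out
}

# water geometry helpers: place two H around O so the dipole bisector points
# along unit vector u (theta from +z realised by the caller), azimuth phi
water_hydrogens <- function(o_pos, u, phi) {
  half <- 104.52 / 2 * pi / 180
  # p: unit vector perpendicular to u, rotated by phi about u
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p1 <- ref - sum(ref * u) * u; p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(u[2] * p1[3] - u[3] * p1[2], u[3] * p1[1] - u[1] * p1[3],
          u[1] * p1[2] - u[2] * p1[1])
  p <- cos(phi) * p1 + sin(phi) * p2
  oh <- 0.9572
  list(h1 = o_pos + oh * (cos(half) * u + sin(half) * p),
       h2 = o_pos + oh * (cos(half) * u - sin(half) * p))
}

# unit vector at angle theta_deg from +z with azimuth phi
dir_from_theta <- function(theta_deg, phi) {
  th <- theta_deg * pi / 180
  c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
}

# continuous-time telegraph state sampled on a frame grid: exponential
# holding times with mean hold_ps, states alternate 1/2
telegraph_states <- function(n_frames, dt, hold_ps, start_state = 1L) {
  if (hold_ps <= 0) return(rep(start_state, n_frames))
  total <- n_frames * dt
  tflip <- cumsum(stats::rexp(ceiling(total / hold_ps * 2) + 20, 1 / hold_ps))
  while (tflip[length(tflip)] < total)
    tflip <- c(tflip, tflip[length(tflip)] +
                 stats::rexp(20, 1 / hold_ps) |> cumsum())
  tmid <- (seq_len(n_frames) - 0.5) * dt
  n_before <- findInterval(tmid, tflip)
  as.integer((start_state - 1L + n_before) %% 2L + 1L)
}

#' Generate a dual-ion triplet trajectory
#'
#' Emits a geometrically valid bilayer-frame trajectory of dual-occupancy
#' episodes: two potassium ions on the two pore sites bridged by 1 or 2
#' interlayer waters. Episode bridge counts are Bernoulli(fraction_n1),
#' episode lifetimes exponential with the given means, and the water dipole
#' orientation follows a continuous-time telegraph process between the two
#' coordination states (mean angles `mu_n1`/`mu_n2`) whose full-cycle rate
#' is the requested flip rate. Episodes are separated by single-occupancy
#' gaps.
#'
#' @param fraction_n1 probability an episode is single-water bridged.
#' @param lifetime_n1,lifetime_n2 mean episode lifetimes, ps.
#' @param flip_rate_n1,flip_rate_n2 orientation switching frequency, GHz.
#' @param n_episodes number of episodes.
#' @param timestep_ps frame spacing; must resolve the flip rates
#'   (timestep < 1/(4 f)).
#' @param gap_ps single-occupancy gap between episodes.
#' @param mu_n1,mu_n2 `c(state1, state2)` mean dipole angles, degrees.
#' @param angle_sd dipole angle jitter, degrees.
#' @param d interlayer distance, Angstrom.
#' @param seed RNG seed.
#' @return an `md_trajectory` with the ground-truth episode table in
#'   attribute `"ground_truth"`.
#' @export
gen_triplet_trajectory <- function(fraction_n1 = 0.513, lifetime_n1 = 300,
                                   lifetime_n2 = 2074, flip_rate_n1 = 578,
                                   flip_rate_n2 = 89.3, n_episodes = 100,
                                   timestep_ps = 1, gap_ps = 10,
                                   mu_n1 = c(60, 120), mu_n2 = c(40, 120),
                                   angle_sd = 6, d = 3.35, seed = 1) {
  hold1 <- 1000 / (2 * flip_rate_n1)   # GHz -> mean holding time in ps
  hold2 <- 1000 / (2 * flip_rate_n2)
  atoms <- data.frame(
    id = 1:8,
    element = c("K", "K", "O", "H", "H", "O", "H", "H"),
    role = c("ionK", "ionK", "waterO", "waterH", "waterH",
             "waterO", "waterH", "waterH"),
    mol = c(NA, NA, 1L, 1L, 1L, 2L, 2L, 2L))
  z1 <- 0; z2 <- d
  park_ion <- c(0, 0, -8)        # unbound ion position
  park_w <- list(c(8, 8, d / 2), c(-8, 8, d / 2))
  build <- function() {
    n_i <- stats::rbinom(n_episodes, 1, fraction_n1)
    n_waters <- ifelse(n_i == 1, 1L, 2L)
    life <- ifelse(n_waters == 1,
                   stats::rexp(n_episodes, 1 / lifetime_n1),
                   stats::rexp(n_episodes, 1 / lifetime_n2))
    frames_ep <- pmax(1L, round(life / timestep_ps))
    frames_gap <- max(1L, round(gap_ps / timestep_ps))
    nf <- sum(frames_ep) + (n_episodes + 1) * frames_gap
    co <- array(0, c(8, 3, nf))
    f <- 0L
    gt <- data.frame(n_waters = n_waters,
                     lifetime_ps = frames_ep * timestep_ps,
                     flip_rate_GHz = ifelse(n_waters == 1, flip_rate_n1,
                                            flip_rate_n2))
    fill_gap <- function(co, f, len) {
      for (g in seq_len(len)) {
        co[1, , f + g] <- c(0, 0, z1)            # K1 waiting on P1
        co[2, , f + g] <- park_ion
        co[3, , f + g] <- park_w[[1]]; co[6, , f + g] <- park_w[[2]]
        hs <- water_hydrogens(park_w[[1]], c(0, 0, 1), 0)
        co[4, , f + g] <- hs$h1; co[5, , f + g] <- hs$h2
        hs <- water_hydrogens(park_w[[2]], c(0, 0, 1), 0)
        co[7, , f + g] <- hs$h1; co[8, , f + g] <- hs$h2
      }
      co
    }
    co <- fill_gap(co, f, frames_gap); f <- f + frames_gap
    for (e in seq_len(n_episodes)) {
      len <- frames_ep[e]
      nw <- n_waters[e]
      hold <- if (nw == 1) hold1 else hold2
      mu <- if (nw == 1) mu_n1 else mu_n2
      st <- telegraph_states(len, timestep_ps, hold,
                             start_state = sample(1:2, 1))
      theta <- mu[st] + stats::rnorm(len, 0, angle_sd)
      theta2 <- mu[3L - st] + stats::rnorm(len, 0, angle_sd)
      phi <- stats::runif(1, 0, 2 * pi)
      for (g in seq_len(len)) {
        co[1, , f + g] <- c(0, 0, z1)
        co[2, , f + g] <- c(0, 0, z2)
        opos <- if (nw == 1) list(c(0.2, 0, d / 2)) else
          list(c(0.8, 0, d / 2), c(-0.8, 0, d / 2))
        co[3, , f + g] <- opos[[1]]
        u <- dir_from_theta(theta[g], phi)
        hs <- water_hydrogens(opos[[1]], u, phi)
        co[4, , f + g] <- hs$h1; co[5, , f + g] <- hs$h2
        if (nw == 2) {
          co[6, , f + g] <- opos[[2]]
          u2 <- dir_from_theta(theta2[g], phi)  # anti-cooperative partner
          hs <- water_hydrogens(opos[[2]], u2, phi)
          co[7, , f + g] <- hs$h1; co[8, , f + g] <- hs$h2
        } else {
          co[6, , f + g] <- park_w[[2]]
          hs <- water_hydrogens(park_w[[2]], c(0, 0, 1), 0)
          co[7, , f + g] <- hs$h1; co[8, , f + g] <- hs$h2
        }
      }
      f <- f + len
      gt$start_frame[e] <- f - len + 1L
      gt$end_frame[e] <- f
      co <- fill_gap(co, f, frames_gap); f <- f + frames_gap
    }
    list(co = co, gt = gt)
  }
  res <- with_seed(seed, build)
  traj <- md_trajectory(atoms, res$co, timestep_ps, box = c(30, 30, 30),
                        layer_z = c(z1, z2), periodic = c(FALSE, FALSE, FALSE))
  attr(traj, "ground_truth") <- res$gt
  attr(traj, "generator_spec") <- generator_spec("triplet_traj", list(
    fraction_n1 = fraction_n1, lifetime_n1 = lifetime_n1,
    lifetime_n2 = lifetime_n2, flip_rate_n1 = flip_rate_n1,
    flip_rate_n2 = flip_rate_n2, n_episodes = n_episodes,
    timestep_ps = timestep_ps, gap_ps = gap_ps, mu_n1 = mu_n1,
    mu_n2 = mu_n2, angle_sd = angle_sd, d = d), seed)
  traj
}

#' Generate a scripted permeation trajectory
#'
#' Two tagged potassium ions replay the dual-ion transport script: the
#' active ion approaches from bulk, is captured at P1 (stage II), hops to P2
#' (stage III), is joined by the second ion at P1 (stage IV, the dominant
#' dwell), and is released past the exit margin (stage V) - one permeation
#' event per cycle, with the joining ion retreating to bulk afterwards
#' (a non-event). The pore axis is periodic so released ions wrap around.
#'
#' @param n_events number of scripted crossings.
#' @param event_duration_ps duration of one full cycle.
#' @param dwell_fractions named fractions of the cycle spent in stages
#'   `II`, `III`, `IV`, `V` (remainder: approach); stage IV defaults to 0.7.
#' @param timestep_ps frame spacing.
#' @param jitter_sd transverse positional jitter, Angstrom.
#' @param d interlayer distance, Angstrom.
#' @param seed RNG seed.
#' @return an `md_trajectory`; ground truth (events, stage frame counts) in
#'   attribute `"ground_truth"`.
#' @export
gen_permeation_trajectory <- function(n_events, event_duration_ps = 2200,
                                      dwell_fractions = c(II = 0.08, III = 0.12,
                                                          IV = 0.7, V = 0.02),
                                      timestep_ps = 2, jitter_sd = 0.15,
                                      d = 3.35, seed = 1) {
  stopifnot(n_events >= 0, sum(dwell_fractions) < 1)
  Lz <- 30
  z1 <- 12; z2 <- z1 + d
  atoms <- data.frame(id = 1:2, element = "K", role = "ionK", mol = NA_integer_)
  n_per <- max(20L, round(event_duration_ps / timestep_ps))
  fr <- function(name) max(1L, round(n_per * dwell_fractions[[name]]))
  n_IV <- fr("IV"); n_II <- fr("II"); n_III <- fr("III")
  n_V <- max(3L, fr("V"))  # release path must sample the exit region
  n_appr <- max(2L, n_per - n_II - n_III - n_IV - n_V)
  build <- function() {
    zA <- c(); zB <- c()
    seg <- function(from, to, n) seq(from, to, length.out = n)
    for (e in seq_len(max(n_events, 0))) {
      # active ion A: bulk -> P1 -> P2 -> exit (wraps); partner B joins at IV
      zA <- c(zA,
              seg(2, z1, n_appr),            # approach from below entry margin
              rep(z1, n_II),                 # stage II at P1
              rep(z2, n_III),                # stage III at P2
              rep(z2, n_IV),                 # stage IV (B at P1)
              seg(z2 + 0.5, Lz + 2 - 1e-6, n_V))  # release past exit, wraps
      zB <- c(zB,
              rep(2, n_appr + n_II + n_III), # B waits in bulk
              rep(z1, n_IV),                 # B captured at P1
              seg(z1, 2, n_V))               # B retreats: not an event
    }
    if (n_events == 0) { zA <- rep(2, 20); zB <- rep(3, 20) }
    nf <- length(zA)
    co <- array(0, c(2, 3, nf))
    co[1, 1, ] <- stats::rnorm(nf, 0, jitter_sd)
    co[1, 2, ] <- stats::rnorm(nf, 0, jitter_sd)
    co[1, 3, ] <- zA %% Lz
    co[2, 1, ] <- stats::rnorm(nf, 0, jitter_sd)
    co[2, 2, ] <- stats::rnorm(nf, 0, jitter_sd)
    co[2, 3, ] <- zB %% Lz
    co
  }
  co <- with_seed(seed, build)
  traj <- md_trajectory(atoms, co, timestep_ps, box = c(30, 30, Lz),
                        layer_z = c(z1, z2), periodic = c(FALSE, FALSE, TRUE))
  attr(traj, "ground_truth") <- list(
    n_events = n_events,
    stage_frames = c(approach = n_appr, II = n_II, III = n_III,
                     IV = n_IV, V = n_V))
  attr(traj, "generator_spec") <- generator_spec("permeation_traj", list(
    n_events = n_events, event_duration_ps = event_duration_ps,
    dwell_fractions = as.list(dwell_fractions), timestep_ps = timestep_ps,
    jitter_sd = jitter_sd, d = d), seed)
  traj
}

#' Generate linear I-V samples
#'
#' Samples I = g (V - U_diff) + noise. The current intercept I_diff is
#' determined by the line (I_diff = -g U_diff); an explicit `I_diff_pA`
#' overrides `U_diff_mV`.
#'
#' @param U_diff_mV reversal potential.
#' @param conductance_nS slope in nS (pA/mV).
#' @param noise_sd current noise, pA.
#' @param n_points number of voltage samples.
#' @param v_range `c(min, max)` applied voltage in mV.
#' @param I_diff_pA optional diffusive current overriding `U_diff_mV`.
#' @param seed RNG seed.
#' @return data.frame `voltage_mV`, `current_pA`.
#' @export
gen_iv <- function(U_diff_mV, conductance_nS, noise_sd = 0, n_points = 11,
                   v_range = c(-100, 100), I_diff_pA = NULL, seed = 1) {
  stopifnot(n_points >= 3, conductance_nS != 0)
  i0 <- if (is.null(I_diff_pA)) -conductance_nS * U_diff_mV else I_diff_pA
  v <- seq(v_range[1], v_range[2], length.out = n_points)
  out <- with_seed(seed, function() data.frame(
    voltage_mV = v,
    current_pA = i0 + conductance_nS * v + stats::rnorm(n_points, 0, noise_sd)))
  attr(out, "generator_spec") <- generator_spec("iv", list(
    U_diff_mV = -i0 / conductance_nS, conductance_nS = conductance_nS,
    I_diff_pA = i0, noise_sd = noise_sd, n_points = n_points,
    v_range = v_range), seed)
  out
}

#' Generate barrier-decomposition training samples
#'
#' dG = a dN_water + b dN_carbonyl + c + N(0, noise_sd), with dN_water
#' uniform on [-5, 0] (dehydration) and dN_carbonyl uniform on [0, 4]
#' (carbonyl coordination gain).
#'
#' @param a,b,c0 water coefficient, carbonyl coefficient and membrane
#'   constant, kcal/mol per unit.
#' @param noise_sd residual noise, kcal/mol.
#' @param n sample count.
#' @param seed RNG seed.
#' @return data.frame `dN_water`, `dN_carbonyl`, `dG`.
#' @export
gen_decomposition_samples <- function(a, b, c0, noise_sd = 0, n = 50, seed = 1) {
  stopifnot(n >= 4)
  out <- with_seed(seed, function() {
    dNw <- stats::runif(n, -5, 0)
    dNc <- stats::runif(n, 0, 4)
    data.frame(dN_water = dNw, dN_carbonyl = dNc,
               dG = a * dNw + b * dNc + c0 + stats::rnorm(n, 0, noise_sd))
  })
  attr(out, "generator_spec") <- generator_spec("decomposition", list(
    a = a, b = b, c = c0, noise_sd = noise_sd, n = n), seed)
  out
}
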