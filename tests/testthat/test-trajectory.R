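test_that("trajectories round-trip through multi-frame XYZ plus sidecar", {
  tt <- gen_triplet_trajectory(n_episodes = 3, timestep_ps = 5,
                               lifetime_n1 = 60, lifetime_n2 = 80, seed = 2)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  meta <- withr::local_tempfile(fileext = ".yaml")
  write_trajectory_xyz(tt, xyz, meta)
  back <- read_trajectory_xyz(xyz, meta)
  expect_equal(back$atoms$role, tt$atoms$role)
  expect_equal(back$atoms$mol, tt$atoms$mol)
  expect_equal(back$timestep_ps, tt$timestep_ps)
  expect_equal(back$layer_z, tt$layer_z)
  expect_equal(back$coords, tt$coords, tolerance = 1e-5)
  expect_equal(back$times, tt$times, tolerance = 1e-6)
})

test_that("site occupancy follows the axial and radial cutoffs", {
  atoms <- ion_atoms(2)
  # ion 1 exactly on plane 1 at the axis; ion 2 on plane 2
  fr <- list(rbind(c(0, 0, 0), c(0.5, 0, 3.35)),    # dual occupancy
             rbind(c(0, 0, 0), c(0, 0, 20)),        # only P1
             rbind(c(0, 4.5, 0), c(0, 0, 20)),      # radially unbound
             rbind(c(0, 0, 1.8), c(0, 0, 20)))      # axially unbound
  tr <- tiny_traj(fr, atoms)
  occ <- assign_site_occupancy(tr)
  expect_equal(unname(occ[1, ]), c(1L, 2L))
  expect_equal(unname(occ[2, ]), c(1L, NA))
  expect_true(all(is.na(occ[3, ])))
  expect_true(all(is.na(occ[4, ])))
})

test_that("permeation events are counted with hysteresis and wrap handling", {
  atoms <- ion_atoms(1)
  Lz <- 30; z1 <- 12; z2 <- 15.35
  mk <- function(zs) {
    fr <- lapply(zs, function(z) matrix(c(0, 0, z %% Lz), 1))
    tiny_traj(fr, atoms, box = c(30, 30, Lz), layer_z = c(z1, z2),
              periodic = c(FALSE, FALSE, TRUE))
  }
  # one scripted crossing
  ev <- detect_permeation_events(mk(seq(2, 20, 0.5)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, 1L)
  # capture followed by retreat: no event
  ev0 <- detect_permeation_events(mk(c(seq(2, 12, 0.5), seq(12, 2, -0.5))))
  expect_equal(nrow(ev0), 0)
  # wrap-around path: two full passes via the periodic boundary
  zs <- c(seq(2, 29, 0.5), seq(29.5, 32, 0.5), seq(2.5, 20, 0.5))
  ev2 <- detect_permeation_events(mk(zs))
  expect_equal(nrow(ev2), 2)
  # reverse crossing is signed negative
  evr <- detect_permeation_events(mk(seq(20, 2, -0.5)))
  expect_equal(evr$direction, -1L)
})

test_that("scripted generator ground truth is recovered exactly", {
  with_seed(31, function() {
    for (i in 1:25) {
      n <- sample(0:6, 1)
      pt <- gen_permeation_trajectory(n, event_duration_ps = 400,
                                      timestep_ps = 2,
                                      seed = sample.int(1e6, 1))
      expect_equal(nrow(detect_permeation_events(pt)), n)
    }
  })
})

test_that("stage-IV dwell dominates the scripted event timeline", {
  pt <- gen_permeation_trajectory(10, seed = 5)
  occ <- assign_site_occupancy(pt)
  dual_frac <- mean(!is.na(occ[, 1]) & !is.na(occ[, 2]))
  expect_equal(dual_frac, 0.7, tolerance = 0.02)
})

test_that("hydration numbers count shell waters under the cutoff", {
  # ion with four waters just inside the cutoff and two outside
  n_w <- 6
  atoms <- rbind(ion_atoms(1),
                 data.frame(id = 1 + seq_len(n_w), element = "O",
                            role = "waterO", mol = seq_len(n_w)))
  shell <- rbind(c(3.4, 0, 5), c(-3.4, 0, 5), c(0, 3.4, 5), c(0, -3.4, 5),
                 c(4.1, 0, 5), c(0, 0, 10))
  fr <- list(rbind(c(0, 0, 5), shell))
  tr <- tiny_traj(fr, atoms)
  h <- hydration_number(tr, 1, cutoff = 3.5)
  expect_equal(h$per_frame, 4L)
  # counts are monotone in the cutoff
  cuts <- c(2, 3, 3.5, 4.2, 12)
  counts <- vapply(cuts, function(ct) hydration_number(tr, 1, ct)$mean,
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  # bulk-like shell statistics: Poisson-perturbed shells around 7.3
  mean_target <- 7.3
  ns <- with_seed(7, function() stats::rpois(400, mean_target))
  frames <- lapply(ns, function(k) {
    pos <- matrix(0, 25, 3)
    if (k > 0) {
      u <- matrix(stats::rnorm(3 * k), k)
      u <- u / sqrt(rowSums(u^2)) * 3.0
      pos[seq_len(k), ] <- u
    }
    if (k < 25) pos[(k + 1):25, ] <- matrix(rep(c(12, 12, 12), 25 - k),
                                            ncol = 3, byrow = TRUE)
    rbind(c(0, 0, 0), pos)
  })
  atoms2 <- rbind(ion_atoms(1),
                  data.frame(id = 1 + 1:25, element = "O", role = "waterO",
                             mol = 1:25))
  tr2 <- tiny_traj(frames, atoms2, layer_z = c(0, 3.35))
  h2 <- hydration_number(tr2, 1, cutoff = 3.5)
  se <- stats::sd(h2$per_frame) / sqrt(length(h2$per_frame))
  expect_lt(abs(h2$mean - mean(ns)), 1e-9)      # counts the placed shell
  expect_lt(abs(h2$mean - mean_target), 3 * se + 3 * sqrt(mean_target / 400))
})

test_that("triplet episodes are classified by bridge count and lifetime", {
  # scripted single episode: one bridging water for 300 ps
  tt <- gen_triplet_trajectory(fraction_n1 = 1, lifetime_n1 = 300,
                               n_episodes = 1, timestep_ps = 1, seed = 42)
  # force the episode length to exactly 300 frames via ground truth check
  cl <- classify_triplets(tt)
  gt <- attr(tt, "ground_truth")
  expect_equal(nrow(cl$events), 1)
  expect_equal(cl$events$n_waters, 1L)
  expect_equal(cl$events$lifetime_ps, gt$lifetime_ps[1])
  # an episode without bridging waters is excluded and flagged
  atoms <- rbind(ion_atoms(2),
                 data.frame(id = 3, element = "O", role = "waterO", mol = 1))
  fr <- rep(list(rbind(c(0, 0, 0), c(0, 0, 3.35), c(9, 9, 1.7))), 12)
  tr0 <- tiny_traj(fr, atoms)
  cl0 <- classify_triplets(tr0)
  expect_equal(nrow(cl0$events), 0)
  expect_equal(cl0$summary$n_excluded, 1L)
})

test_that("dipole orientation is geometric and rotation invariant", {
  # hand-built water between two ions on the z axis
  atoms <- rbind(ion_atoms(2),
                 data.frame(id = 3:5, element = c("O", "H", "H"),
                            role = c("waterO", "waterH", "waterH"),
                            mol = c(1L, 1L, 1L)))
  half <- 104.52 / 2 * pi / 180
  oh <- 0.9572
  mk_frame <- function(u, p) {
    o <- c(0.2, 0, 1.675)
    rbind(c(0, 0, 0), c(0, 0, 3.35),
          o, o + oh * (cos(half) * u + sin(half) * p),
          o + oh * (cos(half) * u - sin(half) * p))
  }
  # dipole along +z (parallel to K1->K2): 0 degrees; perpendicular: 90
  tr <- tiny_traj(list(mk_frame(c(0, 0, 1), c(1, 0, 0)),
                       mk_frame(c(1, 0, 0), c(0, 0, 1))), atoms)
  s <- dipole_orientation(tr, 1, c(1, 2))
  expect_equal(s$theta_deg, c(0, 90), tolerance = 1e-9)
  # rigid rotation + translation of every frame leaves theta unchanged
  tt <- gen_triplet_trajectory(fraction_n1 = 0, lifetime_n2 = 120,
                               n_episodes = 2, timestep_ps = 1, seed = 9)
  fr <- episode_frames(tt)
  s1 <- dipole_orientation(tt, 1, c(1, 2), frames = fr)
  R <- with_seed(13, random_rotation)
  s2 <- dipole_orientation(transform_traj(tt, R, c(3, -2, 7)), 1, c(1, 2),
                           frames = fr)
  expect_equal(s2$theta_deg, s1$theta_deg, tolerance = 1e-8)
  # degenerate (collinear) geometry is rejected
  bad <- tiny_traj(list(rbind(c(0, 0, 0), c(0, 0, 3.35),
                              c(0.2, 0, 1.675), c(1.2, 0, 1.675),
                              c(-0.8, 0, 1.675))), atoms)
  expect_error(dipole_orientation(bad, 1, c(1, 2)), "degenerate")
})

test_that("two-mode orientation histograms expose both peaks", {
  tt <- gen_triplet_trajectory(fraction_n1 = 0, lifetime_n2 = 800,
                               n_episodes = 3, timestep_ps = 0.5, seed = 21)
  s <- dipole_orientation(tt, 1, c(1, 2), frames = episode_frames(tt))
  pk <- orientation_peaks(s)
  expect_equal(length(pk), 2)
  expect_lt(abs(pk[1] - 40), 5)
  expect_lt(abs(pk[2] - 120), 5)
})

test_that("switching frequency counts full cycles with debouncing", {
  # square wave alternating every frame at 1 ps: half-cycle each frame
  sq <- structure(list(time_ps = 0:199, timestep_ps = 1,
                       theta_deg = rep(c(40, 140), 100)),
                  class = "orientation_series")
  expect_equal(switching_frequency(sq, debounce = 1), 500, tolerance = 0.01)
  # constant orientation: no switching
  cst <- structure(list(time_ps = 0:99, timestep_ps = 1,
                        theta_deg = rep(40, 100)),
                   class = "orientation_series")
  expect_equal(switching_frequency(cst), 0)
  # all-ambiguous series is rejected
  amb <- structure(list(time_ps = 0:99, timestep_ps = 1,
                        theta_deg = rep(90, 100)),
                   class = "orientation_series")
  expect_error(switching_frequency(amb), "ambiguous")
  # debouncing suppresses single-frame flickers
  fl <- structure(list(time_ps = 0:99, timestep_ps = 1,
                       theta_deg = c(rep(40, 50), 140, rep(40, 49))),
                  class = "orientation_series")
  expect_equal(switching_frequency(fl, debounce = 2), 0)
})
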