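test_that("PMF normalization zeroes the bulk reference and preserves shape", {
  x <- seq(-5, 5, 0.1)
  flat <- pmf_profile(x, rep(3, length(x)))
  norm <- normalize_pmf(flat, c(-5, -3))
  expect_equal(norm$free_energy, rep(0, length(x)))
  # shift invariance
  p <- gen_pmf_potassium()
  shifted <- pmf_profile(p$coordinate, p$free_energy + 5,
                         annotations = p$annotations)
  n1 <- normalize_pmf(p, p$reference_region)
  n2 <- normalize_pmf(shifted, p$reference_region)
  expect_equal(n1$free_energy, n2$free_energy, tolerance = 1e-12)
  # extrema spacing unchanged by normalization
  e1 <- locate_extrema(n1); e2 <- locate_extrema(n2)
  expect_equal(diff(e1$position), diff(e2$position))
  expect_error(normalize_pmf(p, c(100, 110)), "overlap")
})

test_that("locate_extrema finds alternating minima and maxima", {
  x <- seq(-6, 6, 0.05)
  well <- pmf_profile(x, -6 * exp(-x^2 / 2))
  e <- locate_extrema(well)
  expect_equal(nrow(e), 1)
  expect_equal(e$kind, "min")
  expect_equal(e$value, -6, tolerance = 1e-3)
  expect_equal(e$position, 0, tolerance = 0.051)
  # double well: alternation min/max/min
  p <- gen_pmf_potassium()
  ep <- locate_extrema(p)
  expect_equal(ep$kind, c("min", "max", "min"))
  expect_true(all(diff(ep$position) > 0))
  expect_error(locate_extrema(pmf_profile(x, x)), "no interior extremum")
})

test_that("smoothing and prominence pruning stabilize the extremum count under noise", {
  p_noisy <- gen_pmf_potassium(noise_sd = 0.05, seed = 11)
  e_smooth <- locate_extrema(p_noisy, smoothing_window = 7,
                             min_prominence = 1)
  e_clean <- locate_extrema(gen_pmf_potassium())
  expect_equal(sum(e_smooth$kind == "min"), sum(e_clean$kind == "min"))
  expect_equal(sum(e_smooth$kind == "max"), sum(e_clean$kind == "max"))
  # the surviving extrema sit near the true wells and saddle
  expect_equal(sort(e_smooth$position), sort(e_clean$position),
               tolerance = 0.2)
})

test_that("rate-determining barrier matches the layer-hop free energies", {
  expect_equal(rate_determining_barrier(gen_pmf_potassium()), 3.5,
               tolerance = 0.005)
  expect_equal(rate_determining_barrier(gen_pmf_sodium()), 8.9,
               tolerance = 0.005)
  # invariant under a constant shift
  p <- gen_pmf_potassium()
  shifted <- pmf_profile(p$coordinate, p$free_energy + 2.3,
                         annotations = p$annotations)
  expect_equal(rate_determining_barrier(shifted),
               rate_determining_barrier(p), tolerance = 1e-12)
  # invariant under grid refinement (tolerance proportional to step)
  fine <- gen_pmf(c(-6, -6.4), c(0, 3.35), 3.5, grid_step = 0.01)
  expect_equal(rate_determining_barrier(fine), 3.5, tolerance = 0.002)
  # monotone segment between layers: endpoint difference
  x <- seq(-1, 4.5, 0.05)
  mono <- pmf_profile(x, 0.5 * x,
                      annotations = list(L1 = c(-0.5, 0.5), L2 = c(2.85, 3.85)))
  # increasing profile: both window minima sit at the left window edges
  expect_equal(rate_determining_barrier(mono), 0.5 * (2.85 - (-0.5)),
               tolerance = 1e-9)
  expect_error(rate_determining_barrier(mono, list(L1 = c(50, 60), L2 = c(2.85, 3.85))),
               "missing minimum")
  expect_error(rate_determining_barrier(mono, list(L1 = c(-0.5, 0.5))),
               "annotated")
})

test_that("PMF files round-trip through the TSV format", {
  p <- gen_pmf_potassium()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pmf(p, path)
  back <- read_pmf(path)
  expect_equal(back$coordinate, p$coordinate)
  expect_equal(back$free_energy, p$free_energy, tolerance = 1e-12)
})

test_that("VACF second zero recovers the attempt period", {
  # pure cosine: zeros at T0/4 and 3 T0/4
  dt <- 0.002
  vs <- gen_oscillator_velocities(0.4, 0, n_periods = 12, timestep_ps = dt)
  expect_lt(abs(attempt_period_from_vacf(vs) - 0.3), dt)  # one sample interval
  # light damping: within 5% of the undamped value
  vd <- gen_oscillator_velocities(0.4, 0.08, n_periods = 12, timestep_ps = dt)
  expect_equal(attempt_period_from_vacf(vd), 0.3, tolerance = 0.05)
  # white noise has no oscillatory structure
  wn <- velocity_series(with_seed(5, function() stats::rnorm(2000)), dt)
  expect_error(attempt_period_from_vacf(wn), "no oscillatory structure")
})

test_that("velocity series round-trip through the columnar format", {
  vs <- gen_oscillator_velocities(0.4, 0.05, n_periods = 5, timestep_ps = 0.01,
                                  noise_sd = 0.01, seed = 3)
  path <- withr::local_tempfile(fileext = ".dat")
  write_velocity_series(vs, path)
  back <- read_velocity_series(path)
  expect_equal(back$timestep_ps, vs$timestep_ps)
  expect_equal(back$values, vs$values, tolerance = 1e-9)
})

test_that("transition-state rates follow k = tau^-1 exp(-dG/kBT) exactly", {
  expect_equal(permeation_rate(0, 1), 1e12)
  # frozen high-precision value: 1e12 * exp(-1)
  expect_equal(permeation_rate(0.59616, 1, 300), 3.6787944117144233e11,
               tolerance = 1e-12)
  # independent evaluation in log space on random tuples
  with_seed(17, function() {
    for (i in 1:100) {
      dG <- stats::runif(1, 0, 15); tau <- stats::runif(1, 0.05, 5)
      Tk <- stats::runif(1, 250, 400)
      ref <- exp(log(1e12) - log(tau) - dG / (0.0019872 * Tk))
      expect_equal(permeation_rate(dG, tau, Tk), ref, tolerance = 1e-12)
    }
  })
  # strictly decreasing in the barrier
  ks <- vapply(seq(0, 10, 0.5), permeation_rate, numeric(1), tau_ps = 1)
  expect_true(all(diff(ks) < 0))
  expect_error(permeation_rate(1, -1), "tau")
})

test_that("selectivity ratio compares the two ions' rates", {
  expect_equal(selectivity_ratio(5, 5), 1)
  k_K <- permeation_rate(3.5, 1); k_Na <- permeation_rate(8.9, 1)
  sr <- selectivity_ratio(k_K, k_Na)
  expect_equal(sr, exp(5.4 / kB300), tolerance = 1e-12)
  expect_equal(sr, 8.6e3, tolerance = 0.02 * 8.6e3)
  expect_equal(selectivity_ratio(k_K, k_Na) * selectivity_ratio(k_Na, k_K), 1)
  expect_error(selectivity_ratio(0, 1), "positive")
})
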