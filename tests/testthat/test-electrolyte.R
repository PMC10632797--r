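test_that("ideal chemical potential is kBT ln(c)", {
  st <- solution_state(c(K = 1, Cl = 1))
  expect_equal(ideal_mu(st, "K"), 0)
  st_e <- solution_state(c(K = exp(1), Cl = exp(1)))
  expect_equal(ideal_mu(st_e, "K"), kB300, tolerance = 1e-12)
  # additivity: mu(c1) - mu(c2) = kBT ln(c1/c2)
  s1 <- solution_state(c(K = 0.7, Cl = 0.7))
  s2 <- solution_state(c(K = 0.2, Cl = 0.2))
  expect_equal(ideal_mu(s1, "K") - ideal_mu(s2, "K"),
               kB300 * log(0.7 / 0.2), tolerance = 1e-12)
  st0 <- solution_state(c(K = 1, Cl = 1))
  expect_error(ideal_mu(st0, "Na"), "zero concentration")
})

test_that("solution states enforce electroneutrality and positivity", {
  expect_error(solution_state(c(K = 1, Cl = 0.5)), "electroneutrality")
  expect_error(solution_state(c(K = -1, Cl = -1)))
  st <- solution_state(c(K = 0.3, Na = 0.2, Cl = 0.5))
  expect_equal(sum(st$species$valence * st$concentrations), 0)
})

test_that("BMCSL reduces to Carnahan-Starling for equal diameters", {
  eq_sp <- ion_species(c("K", "Na", "Cl"), c(1, 1, -1), c(4.4, 4.4, 4.4))
  for (ctot in c(0.2, 1, 3)) {
    st <- solution_state(c(K = 0.3 * ctot, Na = 0.2 * ctot, Cl = 0.5 * ctot),
                         species = eq_sp)
    rho <- st$concentrations * kpore_constants$molar_to_A3
    eta <- pi / 6 * sum(rho * 4.4^3)
    cs <- kB300 * eta * (8 - 9 * eta + 3 * eta^2) / (1 - eta)^3
    for (s in c("K", "Na", "Cl"))
      expect_equal(hs_mu(st, s), cs, tolerance = 1e-7)
  }
})

test_that("hard-sphere term vanishes at dilution and grows with packing", {
  st_dilute <- solution_state(c(K = 1e-8, Cl = 1e-8))
  expect_lt(abs(hs_mu(st_dilute, "K")), 1e-7)
  mus <- vapply(c(0.25, 0.5, 1, 2, 4), function(ctot) {
    hs_mu(solution_state(c(K = ctot, Cl = ctot)), "K")
  }, numeric(1))
  expect_true(all(diff(mus) > 0))
})

test_that("MSA screening parameter matches the restricted closed form", {
  with_seed(23, function() {
    for (i in 1:50) {
      sig <- stats::runif(1, 3, 7)
      c1 <- stats::runif(1, 1e-3, 2)
      sp <- ion_species(c("K", "Na", "Cl"), c(1, 1, -1), rep(sig, 3))
      c2 <- stats::runif(1, 0, 1)
      st <- solution_state(c(K = c1, Na = c2, Cl = c1 + c2),
                           species = sp)
      rho <- st$concentrations * kpore_constants$molar_to_A3
      kappa <- sqrt(4 * pi * kpore:::bjerrum_length(st) *
                      sum(rho * st$species$valence^2))
      closed <- (sqrt(1 + 2 * kappa * sig) - 1) / (2 * sig)
      expect_equal(msa_gamma(st), closed, tolerance = 1e-10)
    }
  })
})

test_that("uncharged species carry no electrostatic excess", {
  sp <- ion_species(c("K", "Na", "Cl"), c(0, 0, 0), c(5.6, 4.7, 6.4))
  st <- solution_state(c(K = 1, Na = 1, Cl = 1), species = sp)
  expect_equal(msa_gamma(st), 0)
  expect_equal(msa_mu(st, "K"), 0)
})

test_that("activity coefficients approach the Debye-Hueckel limiting law", {
  lB <- NULL
  ratios <- vapply(c(1e-4, 1e-5, 1e-6), function(c0) {
    st <- solution_state(c(K = c0, Cl = c0))
    lB <<- kpore:::bjerrum_length(st)
    rho <- st$concentrations * kpore_constants$molar_to_A3
    kappa <- sqrt(4 * pi * lB * sum(rho))
    ln_gamma <- (msa_mu(st, "K") + msa_mu(st, "Cl")) / (2 * kB300)
    ln_gamma / (-lB * kappa / 2)
  }, numeric(1))
  expect_true(all(diff(abs(ratios - 1)) < 0))   # converging to the law
  expect_lt(abs(ratios[3] - 1), 0.01)
})

test_that("chemical potentials form an exact gradient (Gibbs-Duhem)", {
  # Maxwell symmetry d mu_i / d c_j = d mu_j / d c_i for the excess terms
  base <- c(K = 0.8, Na = 0.4, Cl = 1.2)
  h <- 1e-4
  mu_at <- function(conc, s) {
    st <- solution_state(conc, neutrality_tol = 1)
    hs_mu(st, s) + msa_mu(st, s)
  }
  for (pair in list(c("K", "Na"), c("K", "Cl"))) {
    i <- pair[1]; j <- pair[2]
    cp <- base; cp[j] <- cp[j] + h
    cm <- base; cm[j] <- cm[j] - h
    dij <- (mu_at(cp, i) - mu_at(cm, i)) / (2 * h)
    cp2 <- base; cp2[i] <- cp2[i] + h
    cm2 <- base; cm2[i] <- cm2[i] - h
    dji <- (mu_at(cp2, j) - mu_at(cm2, j)) / (2 * h)
    expect_equal(dij, dji, tolerance = 1e-3)
  }
})

test_that("reservoir free energy is extensive and favours mixing", {
  ideal_only <- c(ideal = TRUE, hs = FALSE, msa = FALSE)
  st <- solution_state(c(K = 1, Cl = 1))
  expect_equal(reservoir_free_energy(st, 1, ideal_only), 0)
  st2 <- solution_state(c(K = 0.4, Na = 0.3, Cl = 0.7))
  expect_equal(reservoir_free_energy(st2, 2),
               2 * reservoir_free_energy(st2, 1), tolerance = 1e-12)
  g_mixed <- reservoir_free_energy(
    solution_state(c(K = 0.5, Na = 0.5, Cl = 1)), 1, ideal_only)
  g_pure <- reservoir_free_energy(
    solution_state(c(K = 1, Cl = 1)), 1, ideal_only)
  expect_lt(g_mixed, g_pure)
  # density route agrees with the Euler route on the ideal part up to the
  # extensive -n kBT term (which cancels in any mixing difference)
  g_e <- reservoir_free_energy(st2, 1, ideal_only)
  g_d <- reservoir_free_energy(st2, 1, ideal_only, route = "density")
  expect_equal(g_e - g_d, kB300 * sum(st2$concentrations), tolerance = 1e-9)
})

test_that("unphysical packing is rejected", {
  sp <- ion_species(c("K", "Cl"), c(1, -1), c(9, 9))
  st <- solution_state(c(K = 3, Cl = 3), species = sp)
  expect_error(hs_mu(st, "K"), "unphysical packing")
})
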