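test_that("carbonyl positions follow the clockwise twist convention", {
  expect_equal(build_layer(0)$carbonyl_positions, c(0L, 2L, 5L, 7L))
  expect_equal(build_layer(1)$carbonyl_positions, sort((c(0, 2, 5, 7) + 1) %% 8))
  for (k in 0:4)
    expect_equal(build_layer(k)$carbonyl_positions,
                 sort((c(0L, 2L, 5L, 7L) + k) %% 8L))
  expect_error(build_layer(5), "invalid configuration")
  expect_error(build_layer(-1), "invalid configuration")
  expect_error(build_layer(2.5), "invalid configuration")
})

test_that("every generated layer passes the adjacent-carbonyl dismissal rule", {
  for (k in 0:4) {
    p <- build_layer(k)$carbonyl_positions
    adj <- sum(outer(p, p, function(a, b) (a - b) %% 8L == 1L))
    expect_lt(adj, 2)
  }
  # a run of adjacent carbonyls is dismissed
  expect_false(kpore:::valid_carbonyl_set(c(0, 1, 2, 4)))
  expect_true(kpore:::valid_carbonyl_set(c(0, 2, 5, 7)))
  expect_true(kpore:::valid_carbonyl_set(c(1, 3, 6, 0)))
})

test_that("the carved pore removes 16 atoms with the expected footprint", {
  a0 <- build_layer(0)
  expect_equal(a0$n_removed, 16)
  expect_equal(sum(a0$atoms$element == "O"), 4)
  # printed design size is 9.8 x 9.9 A^2; the carved footprint agrees to ~10%
  expect_lt(abs(prod(a0$footprint) / (9.8 * 9.9) - 1), 0.15)
  # bond-length scaling scales the geometry
  big <- build_layer(0, lattice_bond_length = 1.6)
  expect_equal(big$footprint[1] - 3.4, (a0$footprint[1] - 3.4) * 1.6 / 1.42,
               tolerance = 1e-10)
})

test_that("bilayers are labelled, coaxial and validated", {
  b <- build_bilayer(0, 1, 3.35)
  expect_equal(b$label, "A0A1")
  expect_equal(b$d, 3.35)
  expect_equal(unique(b$layer1$atoms$z), 0)
  expect_equal(unique(b$layer2$atoms$z), 3.35)
  expect_error(build_bilayer(0, 1, -1), "geometry error")
  expect_error(build_bilayer(0, 1, 0), "geometry error")
  # homo-bilayer: identical carbonyl sets
  h <- build_bilayer(4, 4)
  expect_identical(h$layer1$carbonyl_positions, h$layer2$carbonyl_positions)
  # mirror pair equivalent under layer swap
  expect_true(layers_swap_equivalent(build_bilayer(1, 0), build_bilayer(0, 1)))
  expect_false(layers_swap_equivalent(build_bilayer(1, 2), build_bilayer(0, 1)))
})

test_that("configuration enumeration counts 25 ordered and 15 swap-unique", {
  expect_length(enumerate_configs("none"), 25)
  expect_length(enumerate_configs("layer_swap"), 15)
  # oracle: exhaustive pairwise dedup of the 25 ordered labels
  pairs <- expand.grid(m = 0:4, n = 0:4)
  canon <- unique(apply(pairs, 1, function(p) paste(sort(p), collapse = "")))
  expect_length(canon, 15)
  expect_length(enumerate_configs("custom",
                                  predicate = function(...) TRUE), 1)
  expect_error(enumerate_configs("custom"), "predicate")
})

test_that("effective pore area behaves like an excluded-area probe", {
  # unobstructed 10 x 10 window integrates to its area
  expect_equal(effective_pore_area(NULL, 0, 0.05, window = c(0, 10, 0, 10)),
               100, tolerance = 1e-9)
  # carbonyl-functionalized layer: ~32 A^2 at the calibrated probe
  a0 <- build_layer(0)
  area <- effective_pore_area(a0)
  expect_lt(abs(area / 32 - 1), 0.2)
  # functionalization narrows the pore
  expect_lt(area, effective_pore_area(a0, probe_radius = 0) + 1e-9)
  # monotone non-increasing in probe radius, including doubling
  probes <- c(0, 0.2, 0.4, 0.8, 1.6)
  areas <- vapply(probes, function(p) effective_pore_area(a0, p, 0.1),
                  numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  expect_error(effective_pore_area(a0, grid_step = 20), "resolution error")
})

test_that("structure writers round-trip coordinates", {
  b <- build_bilayer(0, 1)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(b, xyz, "xyz")
  lines <- readLines(xyz)
  n_atoms <- nrow(b$layer1$atoms) + nrow(b$layer2$atoms)
  expect_equal(as.integer(lines[1]), n_atoms)
  back <- read_xyz(xyz)
  expect_equal(nrow(back), n_atoms)
  expect_equal(back$x, c(b$layer1$atoms$x, b$layer2$atoms$x), tolerance = 1e-3)
  # write -> read -> write idempotence
  xyz2 <- withr::local_tempfile(fileext = ".xyz")
  write_structure(b, xyz2, "xyz")
  expect_identical(readLines(xyz), readLines(xyz2))
  # PDB parses with a standard reader; one residue per layer
  write_structure(b, pdb, "pdb")
  parsed <- bio3d::read.pdb(pdb)
  expect_equal(nrow(parsed$atom), n_atoms)
  expect_setequal(unique(parsed$atom$resno), c(1, 2))
  expect_equal(parsed$atom$x, c(b$layer1$atoms$x, b$layer2$atoms$x),
               tolerance = 1e-3)
  expect_error(write_structure(b, xyz, "gro"))
})
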