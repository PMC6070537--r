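cell <- plla_alpha_cell()
spec <- block_spec(6000, 5000)

test_that("chain folding count follows from lamellar thickness and helix rise", {
  sf <- stems_and_folds(spec, cell, 2.5)
  expect_identical(sf$stems, 10L)
  expect_identical(sf$folds, 9L)

  # one stem's worth of mass -> single unfolded stem
  m_per_stem <- 2.5 / (cell$c / cell$helix_monomers_per_c)
  one <- block_spec(ceiling(m_per_stem) * 72, 5000)
  sf1 <- stems_and_folds(one, cell, 2.5)
  expect_identical(sf1$stems, 1L)
  expect_identical(sf1$folds, 0L)

  # thinner lamella doubles the stem count (hand arithmetic:
  # 83 monomers / 4.328 monomers-per-stem = 19.18 -> 19)
  sf2 <- stems_and_folds(spec, cell, 1.25)
  expect_identical(sf2$stems, 19L)
  expect_identical(sf2$folds, 18L)

  expect_error(stems_and_folds(spec, cell, -1), "positive")
})

test_that("architecture is self-consistent: stems x monomers/stem ~ N", {
  for (t in c(1.25, 2.0, 2.5, 3.5)) {
    sf <- stems_and_folds(spec, cell, t)
    expect_lt(abs(sf$stems * sf$monomers_per_stem - spec$n_hydrophobic),
              sf$monomers_per_stem)  # within one monomer per stem
    expect_identical(sf$folds, sf$stems - 1L)
    expect_gte(sf$stems, 1L)
  }
})

test_that("grafting density and anchor distance reproduce the brush geometry", {
  sigma <- grafting_density(cell, 10L)
  expect_equal(sigma, 0.3046, tolerance = 1e-3)
  expect_equal(anchor_distance(sigma), 1.81, tolerance = 0.01)

  # reciprocal of the single-stem cross-section
  expect_equal(grafting_density(cell, 1L), 3.0457, tolerance = 1e-4)
  # doubling the ab-area halves sigma
  cell2 <- unit_cell(2 * cell$a, cell$b, cell$c, cell$chains_per_cell)
  expect_equal(grafting_density(cell2, 10L), sigma / 2)

  expect_equal(anchor_distance(1), 1)
  expect_equal(anchor_distance(0.25), 2)
  expect_error(anchor_distance(0), "positive")
})

test_that("anchor distance round trip: D^2 * sigma = 1 for any stem count", {
  for (s in c(1L, 2L, 5L, 10L, 37L)) {
    sigma <- grafting_density(cell, s)
    expect_equal(anchor_distance(sigma)^2 * sigma, 1, tolerance = 1e-12)
  }
})

test_that("Flory radius and brush thickness follow the scaling laws", {
  expect_equal(flory_radius(113, 0.35), 5.95, tolerance = 0.05 / 5.95)
  expect_equal(flory_radius(1, 0.7), 0.7)
  expect_equal(flory_radius(32, 1.0), 8.0)  # 32^(3/5) = 2^3

  expect_equal(brush_thickness(113, 0.35, 1.81), 13.2, tolerance = 0.2 / 13.2)
  expect_equal(brush_thickness(100, 1.0, 8.0), 25.0)  # 8^(2/3) = 4
  # D = a: exponents cancel, fully stretched
  expect_equal(brush_thickness(50, 0.4, 0.4), 50 * 0.4)

  # monotone decreasing in D, linear in N; R_F monotone in N
  d <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(brush_thickness(113, 0.35, d)) < 0))
  expect_equal(brush_thickness(226, 0.35, 1.81),
               2 * brush_thickness(113, 0.35, 1.81))
  expect_true(all(diff(flory_radius(1:50, 0.35)) > 0))
})

test_that("brush/mushroom classification uses D < R_F with boundary mushroom", {
  expect_identical(brush_regime(1.81, 5.95), "brush")
  expect_identical(brush_regime(10, 5.95), "mushroom")
  expect_identical(brush_regime(5.95, 5.95), "mushroom")
})

test_that("mass-balance layer thicknesses match hand-computed values", {
  rho <- cell_density(cell, 72)
  expect_equal(rho, 1.261, tolerance = 1e-3)
  # crystal layer from cell density, brush layer from amorphous PEG
  expect_equal(layer_thickness_from_mass(0.3046, 6000, rho), 2.41,
               tolerance = 0.005)
  expect_equal(layer_thickness_from_mass(0.3046, 5000, 1.12), 2.26,
               tolerance = 0.005)
  # linear in sigma
  expect_equal(layer_thickness_from_mass(0.6092, 6000, rho),
               2 * layer_thickness_from_mass(0.3046, 6000, rho))
})

test_that("full architecture chain reproduces the printed shell numbers", {
  arch <- crystal_architecture(spec, cell, 2.5)
  expect_identical(arch$stems_per_chain, 10L)
  expect_identical(arch$folds_per_chain, 9L)
  expect_equal(arch$sigma, 0.30, tolerance = 0.01 / 0.30)
  expect_equal(arch$anchor_distance_D, 1.81, tolerance = 0.02 / 1.81)
  expect_equal(arch$flory_radius_RF, 5.95, tolerance = 0.05 / 5.95)
  expect_equal(arch$brush_thickness_L, 13.2, tolerance = 0.2 / 13.2)
  expect_identical(arch$regime, "brush")
})

test_that("degree of polymerization uses floor of Mn over repeat mass", {
  expect_identical(spec$n_hydrophilic, 113)   # 5000 / 44
  expect_identical(spec$n_hydrophobic, 83)    # 6000 / 72
  expect_error(block_spec(30, 5000), "repeat")
})
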