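# Core lattice-MC contracts on small systems: construction, energy
# bookkeeping, conservation, crystalline-bond detection, clustering.

small_cfg <- mc_config(box = c(12L, 12L, 12L), droplet_radius = 4,
                       n_chains = 8L, block_lengths = c(4L, 6L),
                       seed = 2L)

test_that("system construction places blocks on the correct droplet sides", {
  cfg <- mc_config(box = c(24L, 24L, 24L), droplet_radius = 8,
                   n_chains = 20L, seed = 5L)
  sys <- build_system(cfg)
  expect_valid_system(sys)
  N <- cfg$n_a + cfg$n_b
  d <- sweep(sys$pos, 2, cfg$droplet_center)
  for (k in 1:3) d[, k] <- wrap_diff(d[, k], cfg$box[k])
  r <- sqrt(rowSums(d^2))
  idx <- rep(seq_len(N), cfg$n_chains)
  expect_true(all(r[idx > cfg$n_a] < cfg$droplet_radius))   # B inside
  expect_true(all(r[idx <= cfg$n_a] >= cfg$droplet_radius)) # A outside
  # block junctions sit within ~1 site of the interface radius
  junction_r <- r[idx == cfg$n_a + 1]
  expect_true(all(abs(junction_r - cfg$droplet_radius) <= 2))
})

test_that("infeasible packing raises a construction error with the count", {
  cfg <- mc_config(box = c(16L, 16L, 16L), droplet_radius = 5,
                   n_chains = 200L, seed = 1L)
  expect_error(build_system(cfg), "infeasible packing: placed only")
})

test_that("incremental energy equals brute-force recomputation", {
  sys <- build_system(small_cfg)
  # C++ full recomputation vs the independent R oracle, at t = 0
  expect_equal(system_energy(sys)[1:3], oracle_energy_counts(sys)[1:3])
  e_prev <- system_energy(sys)$energy
  for (chunk in 1:4) {
    sys <- mc_run(sys, 25)
    e_now <- system_energy(sys)$energy
    # incremental bookkeeping matches full recomputation to machine precision
    expect_equal(attr(sys, "delta_e"), e_now - e_prev, tolerance = 1e-12)
    # and the C++ full recomputation matches the R brute-force oracle
    expect_equal(system_energy(sys)[1:3], oracle_energy_counts(sys)[1:3])
    e_prev <- e_now
  }
})

test_that("sweeps conserve monomers, chains, composition and connectivity", {
  sys <- build_system(small_cfg)
  pos0 <- sys$pos
  sys <- mc_run(sys, 300)
  expect_valid_system(sys)
  expect_identical(dim(sys$pos), dim(pos0))
  expect_gt(attr(sys, "accepted"), 0)
})

test_that("single-chain conformation statistics match exhaustive enumeration", {
  # A1-B2 trimer, athermal mixing (ep = B = 0): only the rigidity
  # penalty acts.  Exhaustive enumeration over bond-direction pairs
  # with excluded volume gives the Boltzmann probability that the two
  # bonds are collinear.
  tstar <- 3.6
  n_straight <- 0; z_straight <- 0; z_bent <- 0
  for (i in seq_len(nrow(nb_offsets))) {
    for (j in seq_len(nrow(nb_offsets))) {
      v1 <- nb_offsets[i, ]; v2 <- nb_offsets[j, ]
      if (all(v2 == -v1)) next             # monomer 3 on monomer 1
      if (all(v2 == v1)) z_straight <- z_straight + 1
      else z_bent <- z_bent + exp(-1 / tstar)
    }
  }
  p_exact <- z_straight / (z_straight + z_bent)

  cfg <- mc_config(box = c(8L, 8L, 8L), droplet_radius = 0.5,
                   n_chains = 1L, block_lengths = c(1L, 2L),
                   ep_over_ec = 0, b_over_ec = 0, seed = 3L)
  sys <- structure(list(
    pos = matrix(c(3L, 3L, 3L, 3L, 3L, 4L, 3L, 3L, 5L),
                 nrow = 3, byrow = TRUE), cfg = cfg),
    class = "chain_system")
  set.seed(99)
  n_samples <- 8000; straight <- 0
  for (s in seq_len(n_samples)) {
    sys <- mc_run(sys, 5)
    v1 <- wrap_diff(sys$pos[2, ] - sys$pos[1, ], cfg$box)
    v2 <- wrap_diff(sys$pos[3, ] - sys$pos[2, ], cfg$box)
    if (all(v1 == v2)) straight <- straight + 1
  }
  p_mc <- straight / n_samples
  expect_equal(p_mc, p_exact, tolerance = 0.2)  # ~0.052 +/- MC error
})

test_that("crystalline-bond detection matches the hand-enumerable stem bundle", {
  # 3 x 3 bundle of straight 5-bond B stems along z (chains = 1 A + 6 B)
  cfg <- mc_config(box = c(12L, 12L, 12L), droplet_radius = 0.5,
                   n_chains = 9L, block_lengths = c(1L, 6L), seed = 1L)
  pos <- NULL
  for (sx in 2:4) for (sy in 2:4) {
    # A cap on top, B monomers descending in z
    chain <- cbind(sx, sy, 8:2)
    pos <- rbind(pos, chain)
  }
  sys <- make_system(matrix(as.integer(pos), ncol = 3), cfg)

  # C++ per-bond parallel counts equal the brute-force oracle
  bonds_all <- detect_crystalline_bonds(sys, min_parallel = 1)
  oracle <- oracle_parallel_counts(sys)
  got <- setNames(bonds_all$n_parallel, bonds_all$monomer)
  expect_equal(got[names(oracle)], oracle[names(oracle)],
               ignore_attr = TRUE)

  # centre-stem interior bonds see all 24 neighbours; corner end bonds 6
  expect_equal(max(bonds_all$n_parallel), 24)
  expect_equal(min(bonds_all$n_parallel), 6)

  # at min_parallel = 4 every bond in the bundle is crystalline
  b4 <- detect_crystalline_bonds(sys, min_parallel = 4)
  expect_equal(nrow(b4), 9 * 5)
  expect_equal(length(unique(b4$cluster)), 1)  # one connected nucleus

  # a single isolated straight chain has no crystalline bonds
  cfg1 <- mc_config(box = c(12L, 12L, 12L), droplet_radius = 0.5,
                    n_chains = 1L, block_lengths = c(1L, 6L), seed = 1L)
  iso <- make_system(matrix(as.integer(cbind(6, 6, 8:2)), ncol = 3), cfg1)
  expect_equal(nrow(detect_crystalline_bonds(iso, min_parallel = 1)), 0)
})

test_that("clustering separates distant bundles and computes nucleus geometry", {
  cfg <- mc_config(box = c(20L, 20L, 20L), droplet_radius = 0.5,
                   droplet_center = c(0, 0, 0),
                   n_chains = 8L, block_lengths = c(1L, 6L), seed = 1L)
  pos <- NULL
  for (sx in 2:3) for (sy in 2:3) pos <- rbind(pos, cbind(sx, sy, 8:2))
  for (sx in 12:13) for (sy in 12:13) pos <- rbind(pos, cbind(sx, sy, 8:2))
  sys <- make_system(matrix(as.integer(pos), ncol = 3), cfg)
  bonds <- detect_crystalline_bonds(sys, min_parallel = 3)
  expect_equal(length(unique(bonds$cluster)), 2)
  nuc <- cluster_nuclei(bonds)
  expect_equal(nrow(nuc), 2)
  # R_nucleus formula base case: a cluster of n bonds at v_bond = 1
  expect_equal(nuc$R_nucleus, (3 * nuc$size / (4 * pi))^(1 / 3))
  expect_true(all(nuc$d_cm >= 0))
  # stems are along z; check orientation is P2 of the radial cosine
  expect_true(all(nuc$orientation >= -0.5 & nuc$orientation <= 1))
})

test_that("isotropic bond directions give zero orientation order", {
  set.seed(11)
  # Monte-Carlo average of P2 under uniformly sampled directions
  u <- matrix(rnorm(3 * 20000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  p2 <- p2_legendre(u[, 3])
  expect_equal(mean(p2), 0, tolerance = 0.02)
  # perfectly radial bundle has orientation 1
  expect_equal(p2_legendre(1), 1)
  expect_equal(p2_legendre(0), -0.5)
})

test_that("radial profile equals a direct binning of hand-built records", {
  nuc <- data.frame(cluster = 1:5, size = c(4, 9, 16, 25, 36),
                    R_nucleus = (3 * c(4, 9, 16, 25, 36) / (4 * pi))^(1 / 3),
                    d_cm = c(0.5, 1.5, 1.7, 3.2, 9.9),
                    orientation = c(0.1, 0.4, 0.6, -0.2, 0))
  prof <- radial_profile(nuc, bin_edges = 0:10)
  expect_equal(prof$n_samples[1:4], c(1L, 2L, 0L, 1L))
  expect_equal(prof$mean_R_nucleus[2],
               mean(nuc$R_nucleus[c(2, 3)]))
  expect_equal(prof$mean_orientation[2], mean(c(0.4, 0.6)))
  expect_equal(prof$mean_R_nucleus[10], nuc$R_nucleus[5])
  # empty input gives an all-empty profile
  empty <- radial_profile(nuc[0, ], bin_edges = 0:10)
  expect_true(all(empty$n_samples == 0))
})
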