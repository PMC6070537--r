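test_that("generators are bit-reproducible from (spec, seed)", {
  a <- gen_circulation(list(noise_cv = 0.2), seed = 77)
  b <- gen_circulation(list(noise_cv = 0.2), seed = 77)
  expect_identical(a, b)
  fc1 <- gen_force_curve(list(noise_sd_nN = 1), seed = 3)
  fc2 <- gen_force_curve(list(noise_sd_nN = 1), seed = 3)
  expect_identical(fc1, fc2)
  p1 <- gen_organ_panel(seed = 12)
  p2 <- gen_organ_panel(seed = 12)
  expect_identical(p1, p2)
})

test_that("force-curve generator ground truth is recoverable", {
  fc <- gen_force_curve(list(slope_N_per_m = 4.2, noise_sd_nN = 0))
  expect_equal(shell_stiffness(fc, fit_range = c(6, 14)), 4.2,
               tolerance = 1e-10)
  # closed-form chain: slope implied by the dry-shell modulus
  g <- shell_geometry(90, 4.5, 0.33)
  k <- stiffness_from_modulus(11.5e9, g)
  fc2 <- gen_force_curve(list(slope_N_per_m = k, noise_sd_nN = 0))
  E <- youngs_modulus_from_stiffness(shell_stiffness(fc2, c(6, 14)), g)
  expect_equal(E, 11.5e9, tolerance = 0.01)
})

test_that("replicate averaging shrinks the stiffness spread like 1/sqrt(n)", {
  set.seed(2024)
  one_mean <- function(n) {
    ks <- vapply(1:n, function(i)
      shell_stiffness(gen_force_curve(list(slope_N_per_m = 6.3,
                                           noise_sd_nN = 2)),
                      fit_range = c(6, 14)), numeric(1))
    mean(ks)
  }
  m1 <- replicate(60, one_mean(1))
  m14 <- replicate(60, one_mean(14))
  ratio <- sd(m1) / sd(m14)
  expect_gt(ratio, sqrt(14) * 0.6)
  expect_lt(ratio, sqrt(14) * 1.6)
})

test_that("thermogram generator areas integrate back within tolerance", {
  tg <- gen_thermogram(list(area_crystal = 60.97, area_brush = 15))
  expect_equal(melting_enthalpy(tg, c(120, 160)), 60.97, tolerance = 1e-3)
  expect_equal(melting_enthalpy(tg, c(35, 65)), 15, tolerance = 1e-3)
  tg0 <- gen_thermogram(list(area_crystal = 0, area_brush = 0))
  expect_equal(crystallinity_from_dsc(tg0, c(120, 160)), 0, tolerance = 1e-8)
  expect_warning(gen_thermogram(list(peak_brush_C = 130)), "overlap")
})

test_that("circulation generator respects cohort structure and errors downstream", {
  coh <- gen_circulation_cohorts(noise_cv = 0, seed = 1)
  expect_equal(fit_one_compartment(coh$day3)$half_life_h, 0.80,
               tolerance = 1e-8)
  expect_equal(fit_one_compartment(coh$day5)$half_life_h, 3.3,
               tolerance = 1e-8)
  expect_equal(fit_one_compartment(coh$day7)$half_life_h, 24.2,
               tolerance = 1e-8)
  expect_equal(length(unique(coh$day3$animal_id)), 4)
  expect_equal(length(unique(coh$day5$animal_id)), 3)
  expect_equal(length(unique(coh$day7$animal_id)), 5)
  expect_true(all(coh$day7$intensity >= 0))

  # fewer than 3 time points: constructor refuses (negative test)
  expect_error(gen_circulation(list(time_h = c(1, 2))), "3 time points")
})

test_that("organ panel generator puts all weight where requested", {
  w <- c(brain = 0, lung = 0, heart = 0, liver = 1, spleen = 0,
         kidney = 0, blood = 0)
  pan <- gen_organ_panel(list(weights = w, noise_cv = 0.05), seed = 8)
  s <- biodistribution_summary(pan)
  for (t in unique(s$relative$time_h)) {
    r <- s$relative[s$relative$time_h == t, ]
    expect_identical(r$organ[which.max(r$mean_fraction)], "liver")
    expect_gt(max(r$mean_fraction), 0.9)
  }
  expect_error(gen_organ_panel(list(weights = w * 2)), "sum to 1")
})
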