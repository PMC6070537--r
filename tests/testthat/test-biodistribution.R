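test_that("treated equal to control gives an all-zero panel", {
  organs <- c("liver", "spleen", "kidney")
  base <- data.frame(organ = rep(organs, 2), mass_g = 1,
                     intensity = 100,
                     group = rep(c("treated", "control"), each = 3),
                     time_h = 24, animal_id = rep(1:2, each = 3))
  pan <- organ_panel(base$organ, base$mass_g, base$intensity, base$group,
                     base$time_h, base$animal_id)
  s <- suppressWarnings(biodistribution_summary(pan))
  expect_true(all(s$per_gram$mean == 0))
})

test_that("a single signal-carrying organ takes relative fraction 1", {
  organs <- c("liver", "spleen", "kidney")
  d <- data.frame(organ = rep(organs, 2), mass_g = c(1.1, 0.1, 0.3),
                  intensity = c(5000, 10, 10, 10, 10, 10),
                  group = rep(c("treated", "control"), each = 3),
                  time_h = 24, animal_id = rep(1:2, each = 3))
  pan <- organ_panel(d$organ, d$mass_g, d$intensity, d$group, d$time_h,
                     d$animal_id)
  s <- biodistribution_summary(pan)
  expect_equal(s$relative$mean_fraction[s$relative$organ == "liver"], 1)
  expect_equal(sum(s$relative$mean_fraction), 1, tolerance = 1e-12)
})

test_that("relative fractions sum to one at every time point", {
  pan <- gen_organ_panel(seed = 5)
  s <- biodistribution_summary(pan)
  for (t in unique(s$relative$time_h)) {
    expect_equal(sum(s$relative$mean_fraction[s$relative$time_h == t]), 1,
                 tolerance = 1e-12)
  }
})

test_that("liver/spleen-dominant enrichment is recovered in the ranking", {
  pan <- gen_organ_panel(seed = 9)
  s <- biodistribution_summary(pan)
  for (t in unique(s$relative$time_h)) {
    r <- s$relative[s$relative$time_h == t, ]
    r <- r[order(-r$mean_fraction), ]
    expect_true(all(r$organ[1:2] %in% c("liver", "spleen")))
    expect_gte(r$mean_fraction[r$organ == "liver"],
               r$mean_fraction[r$organ == "spleen"])
  }
})

test_that("missing control rows are reported with the organ name", {
  d <- data.frame(organ = c("liver", "spleen", "liver"),
                  mass_g = 1, intensity = 10,
                  group = c("treated", "treated", "control"),
                  time_h = 24, animal_id = c(1, 1, 2))
  pan <- organ_panel(d$organ, d$mass_g, d$intensity, d$group, d$time_h,
                     d$animal_id)
  expect_error(biodistribution_summary(pan), "spleen")
})

test_that("crystallinity-halflife table reproduces the rank correlation", {
  res <- crystallinity_halflife_table(list(
    list(days = 3, crystallinity_pct = 18.1, half_life_h = 0.80,
         sd_half_life = 0.46, n_animals = 4),
    list(days = 5, crystallinity_pct = 45.8, half_life_h = 3.3,
         sd_half_life = 0.68, n_animals = 3),
    list(days = 7, crystallinity_pct = 67.0, half_life_h = 24.2,
         sd_half_life = 1.4, n_animals = 5)))
  expect_equal(res$rank_correlation, 1)
  expect_equal(nrow(res$table), 3)

  # identical half-lives: undefined, flagged
  expect_warning(res2 <- crystallinity_halflife_table(list(
    list(days = 3, crystallinity_pct = 10, half_life_h = 5),
    list(days = 5, crystallinity_pct = 20, half_life_h = 5))),
    "undefined")
  expect_true(is.na(res2$rank_correlation))
})

test_that("rank correlation matches a brute-force rank computation", {
  set.seed(31)
  for (rep in 1:5) {
    cr <- sample(c(12, 30, 45, 60, 72))
    hl <- sample(c(0.5, 2, 7, 20, 30))
    groups <- lapply(seq_along(cr), function(i)
      list(days = i, crystallinity_pct = cr[i], half_life_h = hl[i]))
    res <- crystallinity_halflife_table(groups)
    # independent oracle: Pearson correlation of the rank vectors
    oracle <- stats::cor(rank(cr), rank(hl))
    expect_equal(res$rank_correlation, oracle, tolerance = 1e-12)
  }
})
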