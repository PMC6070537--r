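#' Synthetic AFM force curve
#'
#' Piecewise curve emulating shell nanoindentation: a zero-force
#' approach segment followed by a linear contact regime of the requested
#' stiffness, plus additive Gaussian force noise.  The true slope is
#' embedded in the attributes so paired analyses can check recovery.
#'
#' @param spec List of parameters: `slope_N_per_m` (true stiffness,
#'   default 6.33), `max_deformation_nm` (default 10), `approach_nm`
#'   (pre-contact segment, default 5), `n_points` (default 80),
#'   `noise_sd_nN` (additive Gaussian s.d. in nN, default 0).
#' @param seed Optional integer seed for reproducibility.
#' @return A [force_curve()] covering the contact regime only (the
#'   approach segment is prepended at zero force with negative-to-zero
#'   deformation shifted to start at 0); ground truth in
#'   `attr(x, "truth")`.
#' @export
gen_force_curve <- function(spec = list(), seed = NULL) {
  p <- modifyList(list(slope_N_per_m = 6.33, max_deformation_nm = 10,
                       approach_nm = 5, n_points = 80, noise_sd_nN = 0), spec)
  stopifnot(p$slope_N_per_m > 0, p$noise_sd_nN >= 0)
  if (!is.null(seed)) set.seed(seed)
  d <- seq(0, p$approach_nm + p$max_deformation_nm, length.out = p$n_points)
  contact <- p$approach_nm
  f <- ifelse(d <= contact, 0, p$slope_N_per_m * (d - contact))
  f <- f + stats::rnorm(length(f), 0, p$noise_sd_nN)
  out <- force_curve(d, f)
  attr(out, "truth") <- p
  attr(out, "contact_nm") <- contact
  out
}

#' Synthetic DSC thermogram
#'
#' Linear instrumental baseline plus two Gaussian melting endotherms,
#' centered by default at 49.0 deg C (PEG) and 138.9 deg C (PLLA), with
#' requested areas in J/g, sampled at a 10 deg C/min heating rate.
#'
#' @param spec List: `area_brush` (J/g, default 20), `area_crystal`
#'   (J/g, default 60.97), `peak_brush_C` (49.0), `peak_crystal_C`
#'   (138.9), `width_C` (Gaussian sigma, default 3), `baseline_intercept`
#'   and `baseline_slope` (W/g and W/g/degC, default 0), `heating_rate`
#'   (10), `t_min`/`t_max`/`n_points` grid controls, `noise_sd`
#'   (additive W/g noise, default 0).
#' @param seed Optional integer seed.
#' @return A [thermogram()]; ground truth in `attr(x, "truth")`.
#' @export
gen_thermogram <- function(spec = list(), seed = NULL) {
  p <- modifyList(list(area_brush = 20, area_crystal = 60.97,
                       peak_brush_C = 49.0, peak_crystal_C = 138.9,
                       width_C = 3, baseline_intercept = 0,
                       baseline_slope = 0, heating_rate = 10,
                       t_min = 20, t_max = 170, n_points = 1501,
                       noise_sd = 0), spec)
  stopifnot(p$area_brush >= 0, p$area_crystal >= 0, p$width_C > 0)
  if (abs(p$peak_brush_C - p$peak_crystal_C) < 6 * p$width_C)
    warning("melting endotherms overlap substantially")
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(p$t_min, p$t_max, length.out = p$n_points)
  beta <- p$heating_rate / 60  # degC per second
  # a peak of area A J/g corresponds to heat flow A*beta*dnorm (W/g)
  hf <- p$baseline_intercept + p$baseline_slope * tt +
    p$area_brush * beta * stats::dnorm(tt, p$peak_brush_C, p$width_C) +
    p$area_crystal * beta * stats::dnorm(tt, p$peak_crystal_C, p$width_C) +
    stats::rnorm(length(tt), 0, p$noise_sd)
  out <- thermogram(tt, hf, p$heating_rate)
  attr(out, "truth") <- p
  out
}

#' Synthetic blood-circulation cohort
#'
#' Per-animal plasma fluorescence `C0 exp(-k t)` at the standard
#' sampling grid ([circulation_time_grid()]), multiplied by lognormal
#' noise `exp(N(0, noise_cv))`.  Intensities are never negative.
#'
#' @param spec List: `half_life_h` (default 24.2), `c0` (default 100),
#'   `n_animals` (default 5), `noise_cv` (lognormal sigma on the log
#'   scale, default 0.1), `time_h` (default the standard grid), `group`
#'   label.
#' @param seed Optional integer seed.
#' @return A [circulation_series()]; truth in `attr(x, "truth")`.
#' @export
gen_circulation <- function(spec = list(), seed = NULL) {
  p <- modifyList(list(half_life_h = 24.2, c0 = 100, n_animals = 5,
                       noise_cv = 0.1, time_h = circulation_time_grid(),
                       group = NA_character_), spec)
  stopifnot(p$half_life_h > 0, p$n_animals >= 1, p$noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  k <- log(2) / p$half_life_h
  rows <- lapply(seq_len(p$n_animals), function(i) {
    y <- p$c0 * exp(-k * p$time_h) *
      exp(stats::rnorm(length(p$time_h), 0, p$noise_cv))
    data.frame(time_h = p$time_h, intensity = y, animal_id = i,
               group = p$group)
  })
  d <- do.call(rbind, rows)
  out <- circulation_series(d$time_h, d$intensity, d$animal_id, d$group)
  attr(out, "truth") <- p
  out
}

#' Synthetic crystallization-time cohorts
#'
#' Three circulation cohorts mirroring 3-, 5- and 7-day crystallized
#' particles with true half-lives 0.80, 3.3 and 24.2 h and cohort sizes
#' 4, 3 and 5 animals.
#'
#' @param noise_cv Lognormal noise level (default 0.1).
#' @param seed Optional integer seed.
#' @return Named list of [circulation_series()] (`day3`, `day5`, `day7`).
#' @export
gen_circulation_cohorts <- function(noise_cv = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(
    day3 = gen_circulation(list(half_life_h = 0.80, n_animals = 4,
                                noise_cv = noise_cv, group = "3d")),
    day5 = gen_circulation(list(half_life_h = 3.3, n_animals = 3,
                                noise_cv = noise_cv, group = "5d")),
    day7 = gen_circulation(list(half_life_h = 24.2, n_animals = 5,
                                noise_cv = noise_cv, group = "7d"))
  )
}

#' Synthetic organ biodistribution panel
#'
#' Organ signals `dose * weight * lognormal noise + control baseline`
#' for treated animals, and baseline-only controls, with tissue masses
#' drawn from fixed realistic murine ranges.  Default enrichment weights
#' put most of the dose in liver and spleen (reticuloendothelial
#' clearance).
#'
#' @param spec List: `weights` (named, summing to 1 over the 7 organs),
#'   `dose` (default 1e5), `noise_cv` (default 0.15), `baseline`
#'   (control autofluorescence, default 200), `n_animals` (default 3),
#'   `time_h` (default c(24, 48, 72)).
#' @param seed Optional integer seed.
#' @return An [organ_panel()]; truth in `attr(x, "truth")`.
#' @export
gen_organ_panel <- function(spec = list(), seed = NULL) {
  default_w <- c(brain = 0.01, lung = 0.04, heart = 0.02, liver = 0.45,
                 spleen = 0.30, kidney = 0.06, blood = 0.12)
  p <- modifyList(list(weights = default_w, dose = 1e5, noise_cv = 0.15,
                       baseline = 200, n_animals = 3,
                       time_h = c(24, 48, 72)), spec)
  w <- p$weights
  if (abs(sum(w) - 1) > 1e-8) stop("enrichment weights must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  mass_range <- list(brain = c(0.35, 0.45), lung = c(0.12, 0.18),
                     heart = c(0.12, 0.16), liver = c(0.9, 1.3),
                     spleen = c(0.08, 0.12), kidney = c(0.25, 0.35),
                     blood = c(0.8, 1.2))
  organs <- names(w)
  rows <- list()
  aid <- 0L
  for (t in p$time_h) {
    for (grp in c("treated", "control")) {
      for (i in seq_len(p$n_animals)) {
        aid <- aid + 1L
        for (org in organs) {
          m <- stats::runif(1, mass_range[[org]][1], mass_range[[org]][2])
          base <- p$baseline * exp(stats::rnorm(1, 0, p$noise_cv))
          sig <- if (grp == "treated")
            p$dose * w[[org]] * exp(stats::rnorm(1, 0, p$noise_cv)) + base
          else base
          rows[[length(rows) + 1L]] <- data.frame(
            organ = org, mass_g = m, intensity = sig, group = grp,
            time_h = t, animal_id = aid)
        }
      }
    }
  }
  d <- do.call(rbind, rows)
  out <- organ_panel(d$organ, d$mass_g, d$intensity, d$group, d$time_h,
                     d$animal_id)
  attr(out, "truth") <- p
  out
}
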