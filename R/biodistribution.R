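#' Organ fluorescence panel
#'
#' Long-format organ panel from a biodistribution experiment: one row
#' per organ x animal x time point, for treated animals and matched
#' saline controls.
#'
#' @param organ Organ name; one of brain, lung, heart, liver, spleen,
#'   kidney, blood.
#' @param mass_g Tissue mass (g), positive.
#' @param intensity Fluorescence intensity of the homogenate.
#' @param group `"treated"` or `"control"`.
#' @param time_h Collection time point (h).
#' @param animal_id Animal identifier.
#' @return A data.frame of class `organ_panel`.
#' @export
organ_panel <- function(organ, mass_g, intensity, group, time_h, animal_id) {
  organs <- c("brain", "lung", "heart", "liver", "spleen", "kidney", "blood")
  out <- data.frame(organ = organ, mass_g = mass_g, intensity = intensity,
                    group = group, time_h = time_h, animal_id = animal_id)
  if (!all(out$organ %in% organs))
    stop("unknown organ: ", paste(setdiff(out$organ, organs), collapse = ", "))
  if (any(out$mass_g <= 0)) stop("tissue masses must be positive")
  if (!all(out$group %in% c("treated", "control")))
    stop("group must be 'treated' or 'control'")
  class(out) <- c("organ_panel", "data.frame")
  out
}

#' Biodistribution summary tables
#'
#' Per-gram table: control-subtracted intensity per gram of tissue,
#' `(treated - mean control)/mass`, negatives clipped to zero (the clip
#' count is reported).  Relative table: each organ's total
#' (control-subtracted) signal as a fraction of the sum over organs at
#' the same time point, so fractions sum to 1.  Both are summarized as
#' mean +/- s.d. over animals per organ and time.
#'
#' @param panel An [organ_panel()].
#' @return A list of class `biodistribution_summary`: data.frames
#'   `per_gram` (organ, time_h, mean, sd, n) and `relative` (organ,
#'   time_h, mean_fraction, sd, n), plus `n_clipped`.
#' @export
biodistribution_summary <- function(panel) {
  stopifnot(inherits(panel, "organ_panel"))
  tr <- panel[panel$group == "treated", ]
  ct <- panel[panel$group == "control", ]
  n_clipped <- 0L
  rows_pg <- list(); rows_rel <- list()
  for (t in sort(unique(tr$time_h))) {
    trt <- tr[tr$time_h == t, ]
    # per-animal control-subtracted signals
    ids <- unique(trt$animal_id)
    sig <- matrix(NA_real_, length(ids), 0)
    organs <- unique(trt$organ)
    per_gram_m <- matrix(NA_real_, length(ids), length(organs),
                         dimnames = list(ids, organs))
    total_m <- per_gram_m
    for (org in organs) {
      ctl <- ct$intensity[ct$organ == org]
      if (length(ctl) == 0)
        stop("missing control for organ '", org, "' at time ", t, " h")
      bg <- mean(ctl)
      for (i in seq_along(ids)) {
        r <- trt[trt$organ == org & trt$animal_id == ids[i], ]
        if (nrow(r) != 1)
          stop("expected one treated row for organ '", org, "', animal ",
               ids[i], ", time ", t, " h")
        net <- r$intensity - bg
        if (net < 0) { net <- 0; n_clipped <- n_clipped + 1L }
        per_gram_m[i, org] <- net / r$mass_g
        total_m[i, org] <- net
      }
    }
    frac_m <- total_m / rowSums(total_m)
    for (org in organs) {
      rows_pg[[length(rows_pg) + 1L]] <- data.frame(
        organ = org, time_h = t,
        mean = mean(per_gram_m[, org]), sd = stats::sd(per_gram_m[, org]),
        n = length(ids))
      rows_rel[[length(rows_rel) + 1L]] <- data.frame(
        organ = org, time_h = t,
        mean_fraction = mean(frac_m[, org]), sd = stats::sd(frac_m[, org]),
        n = length(ids))
    }
  }
  structure(list(per_gram = do.call(rbind, rows_pg),
                 relative = do.call(rbind, rows_rel),
                 n_clipped = n_clipped),
            class = "biodistribution_summary")
}

#' Crystallinity versus half-life correlation table
#'
#' Summarizes a set of crystallization-time groups (days crystallized,
#' DSC crystallinity, fitted half-life) and the Spearman rank
#' correlation between crystallinity and half-life.
#'
#' @param groups A list; each element a list with `days`,
#'   `crystallinity_pct`, and either a `pk_fit` under `fit` or scalar
#'   `half_life_h` (+ optional `sd_half_life`, `n_animals`).
#' @return A list of class `crystallinity_halflife`: data.frame `table`
#'   and `rank_correlation` (NA with a warning if either variable is
#'   constant).
#' @examples
#' crystallinity_halflife_table(list(
#'   list(days = 3, crystallinity_pct = 18.1, half_life_h = 0.80),
#'   list(days = 5, crystallinity_pct = 45.8, half_life_h = 3.3),
#'   list(days = 7, crystallinity_pct = 67.0, half_life_h = 24.2)))
#' @export
crystallinity_halflife_table <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  rows <- lapply(groups, function(g) {
    if (!is.null(g$fit)) {
      hl <- g$fit$half_life_h; sdh <- g$fit$sd_half_life; n <- g$fit$n_animals
    } else {
      hl <- g$half_life_h
      sdh <- if (is.null(g$sd_half_life)) NA_real_ else g$sd_half_life
      n <- if (is.null(g$n_animals)) NA_integer_ else g$n_animals
    }
    data.frame(days = g$days, crystallinity_pct = g$crystallinity_pct,
               half_life_h = hl, sd_half_life = sdh, n_animals = n)
  })
  tab <- do.call(rbind, rows)
  if (length(unique(tab$half_life_h)) < 2 ||
      length(unique(tab$crystallinity_pct)) < 2) {
    warning("constant variable: rank correlation undefined")
    rho <- NA_real_
  } else {
    rho <- stats::cor(tab$crystallinity_pct, tab$half_life_h,
                      method = "spearman")
  }
  structure(list(table = tab, rank_correlation = rho),
            class = "crystallinity_halflife")
}
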