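#' DSC heating thermogram
#'
#' A differential-scanning-calorimetry heating trace: heat flow per unit
#' sample mass on a monotone increasing temperature grid, acquired at a
#' constant heating rate.  Endotherms are taken as positive heat flow.
#'
#' @param temperature_C Temperature grid (deg C), strictly increasing,
#'   length >= 3.
#' @param heat_flow_W_per_g Heat flow (W/g), same length.
#' @param heating_rate Heating rate (deg C/min), positive.
#' @return An object of class `thermogram` (a data.frame with the two
#'   columns and the heating rate as an attribute).
#' @export
thermogram <- function(temperature_C, heat_flow_W_per_g, heating_rate = 10) {
  stopifnot(length(temperature_C) == length(heat_flow_W_per_g),
            length(temperature_C) >= 3, heating_rate > 0)
  if (any(diff(temperature_C) <= 0))
    stop("temperature grid must be strictly increasing")
  out <- data.frame(temperature_C = temperature_C,
                    heat_flow_W_per_g = heat_flow_W_per_g)
  attr(out, "heating_rate") <- heating_rate
  class(out) <- c("thermogram", "data.frame")
  out
}

#' Melting enthalpy of an endotherm
#'
#' Integrates the baseline-subtracted heat flow over a temperature
#' window and converts to J/g using the heating rate: with heat flow in
#' W/g and dT/dt = beta (deg C/min), `dH = integral(hf - baseline) dT / (beta/60)`.
#' The baseline is the straight line through the trace values at the
#' window endpoints, so the result is invariant to adding any linear
#' function of temperature to the heat flow.
#'
#' @param tg A [thermogram()].
#' @param peak_window Numeric length-2 `c(T_lo, T_hi)` in deg C; must lie
#'   inside the temperature grid.
#' @return Enthalpy in J/g (positive for an endotherm).
#' @export
melting_enthalpy <- function(tg, peak_window) {
  stopifnot(inherits(tg, "thermogram"), length(peak_window) == 2)
  lo <- min(peak_window); hi <- max(peak_window)
  tt <- tg$temperature_C; hf <- tg$heat_flow_W_per_g
  if (lo < min(tt) || hi > max(tt))
    stop("peak_window outside the temperature grid")
  # interpolate trace to the exact window endpoints so the baseline is
  # anchored on the curve, then integrate on the interior grid points
  y_lo <- stats::approx(tt, hf, xout = lo)$y
  y_hi <- stats::approx(tt, hf, xout = hi)$y
  keep <- tt > lo & tt < hi
  x <- c(lo, tt[keep], hi)
  y <- c(y_lo, hf[keep], y_hi)
  base <- y_lo + (y_hi - y_lo) * (x - lo) / (hi - lo)
  beta <- attr(tg, "heating_rate") / 60  # deg C per second
  pracma::trapz(x, y - base) / beta
}

#' Crystallinity from a DSC endotherm
#'
#' Percent crystallinity of the crystallizable block from the melting
#' enthalpy relative to the 100%-crystal reference value (91 J/g for
#' the alpha form of PLLA).
#'
#' @inheritParams melting_enthalpy
#' @param dH_ref Reference melting enthalpy of the fully crystalline
#'   polymer (J/g); default 91.
#' @param mass_fraction Mass fraction of the crystallizable block in the
#'   sample (default 1, i.e. enthalpy already per gram of that block).
#' @return Crystallinity in percent.  A negative integrated enthalpy is
#'   returned as-is with a warning (flagged result).
#' @examples
#' tg <- gen_thermogram(list(area_crystal = 60.97))
#' crystallinity_from_dsc(tg, c(120, 160))
#' @export
crystallinity_from_dsc <- function(tg, peak_window, dH_ref = 91,
                                   mass_fraction = 1) {
  stopifnot(dH_ref > 0, mass_fraction > 0, mass_fraction <= 1)
  dh <- melting_enthalpy(tg, peak_window) / mass_fraction
  if (dh < 0) warning("negative integrated enthalpy; no endotherm in window")
  100 * dh / dH_ref
}
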