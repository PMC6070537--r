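#' AFM force curve
#'
#' A force-deformation record from AFM nanoindentation of a shell:
#' tip-induced deflection (nm, non-negative, increasing) versus force
#' (nN), with optional tip metadata.
#'
#' @param deformation_nm Deformation grid (nm), non-negative, increasing,
#'   length >= 5.
#' @param force_nN Force (nN), same length.
#' @param tip_radius_nm,spring_constant_N_per_m Optional metadata.
#' @return An object of class `force_curve` (a data.frame).
#' @export
force_curve <- function(deformation_nm, force_nN,
                        tip_radius_nm = NA_real_,
                        spring_constant_N_per_m = NA_real_) {
  stopifnot(length(deformation_nm) == length(force_nN),
            length(deformation_nm) >= 5)
  if (any(deformation_nm < 0) || any(diff(deformation_nm) <= 0))
    stop("deformation must be non-negative and strictly increasing")
  out <- data.frame(deformation_nm = deformation_nm, force_nN = force_nN)
  attr(out, "tip_radius_nm") <- tip_radius_nm
  attr(out, "spring_constant_N_per_m") <- spring_constant_N_per_m
  class(out) <- c("force_curve", "data.frame")
  out
}

#' Thin spherical shell geometry
#'
#' @param radius_R Mid-surface radius (nm).
#' @param thickness_h Wall thickness (nm), 0 < h < R.
#' @param poisson_nu Poisson ratio, 0 <= nu < 0.5; default 0.33.
#' @return An object of class `shell_geometry`.
#' @export
shell_geometry <- function(radius_R, thickness_h, poisson_nu = 0.33) {
  stopifnot(radius_R > 0)
  if (thickness_h <= 0 || thickness_h >= radius_R)
    stop("thin-shell violation: need 0 < h < R")
  if (poisson_nu < 0 || poisson_nu >= 0.5)
    stop("poisson ratio must be in [0, 0.5)")
  structure(list(radius_R = radius_R, thickness_h = thickness_h,
                 poisson_nu = poisson_nu), class = "shell_geometry")
}

#' Shell stiffness from a force curve
#'
#' Least-squares slope of force versus deformation over a fit range of
#' the linear shell-compression regime, converted to N/m
#' (nN/nm == N/m).
#'
#' @param fc A [force_curve()].
#' @param fit_range Length-2 deformation interval (nm).  Default: 10% to
#'   80% of the maximum deformation.
#' @return Stiffness k_shell in N/m.
#' @export
shell_stiffness <- function(fc, fit_range = NULL) {
  stopifnot(inherits(fc, "force_curve"))
  d <- fc$deformation_nm
  if (is.null(fit_range)) fit_range <- c(0.1, 0.8) * max(d)
  keep <- d >= min(fit_range) & d <= max(fit_range)
  if (sum(keep) < 3) stop("fewer than 3 points in fit range")
  unname(stats::coef(stats::lm(fc$force_nN[keep] ~ d[keep]))[2])
}

#' Young's modulus from Reissner shell stiffness
#'
#' Point-load stiffness of a thin spherical shell (Reissner):
#' `k = 4 E h^2 / (R sqrt(3 (1 - nu^2)))`, inverted to
#' `E = k R sqrt(3 (1 - nu^2)) / (4 h^2)`.
#'
#' @param k_shell Stiffness (N/m).
#' @param g A [shell_geometry()].
#' @return Young's modulus in Pa.
#' @examples
#' youngs_modulus_from_stiffness(6.33, shell_geometry(90, 4.5))
#' @export
youngs_modulus_from_stiffness <- function(k_shell, g) {
  stopifnot(inherits(g, "shell_geometry"), k_shell >= 0)
  r <- g$radius_R * 1e-9; h <- g$thickness_h * 1e-9
  k_shell * r * sqrt(3 * (1 - g$poisson_nu^2)) / (4 * h^2)
}

#' @rdname youngs_modulus_from_stiffness
#' @param E Young's modulus (Pa).
#' @export
stiffness_from_modulus <- function(E, g) {
  stopifnot(inherits(g, "shell_geometry"), E >= 0)
  r <- g$radius_R * 1e-9; h <- g$thickness_h * 1e-9
  4 * E * h^2 / (r * sqrt(3 * (1 - g$poisson_nu^2)))
}

#' Bending modulus of the shell wall
#'
#' Plate bending rigidity `K = E h^3 / (12 (1 - nu^2))`.
#'
#' @param g A [shell_geometry()].
#' @param E Young's modulus (Pa).
#' @return Bending modulus in J.
#' @examples
#' bending_modulus(shell_geometry(90, 4.5), 11.5e9)
#' @export
bending_modulus <- function(g, E) {
  stopifnot(inherits(g, "shell_geometry"), E >= 0)
  h <- g$thickness_h * 1e-9
  E * h^3 / (12 * (1 - g$poisson_nu^2))
}

#' Energy in units of kT
#'
#' @param K Energy (J).
#' @param T_K Temperature (K), default 298.
#' @return K / (k_B T), dimensionless.
#' @export
in_kBT <- function(K, T_K = 298) {
  stopifnot(T_K > 0)
  K / (1.380649e-23 * T_K)
}

#' Full nanoindentation mechanics chain
#'
#' Stiffness from one or more force curves (replicate-averaged), then
#' Young's modulus and bending modulus for the given geometry.
#'
#' @param curves A [force_curve()] or list of replicates.
#' @param g A [shell_geometry()].
#' @param fit_range Passed to [shell_stiffness()].
#' @param T_K Temperature (K) for the kT conversion.
#' @return A list of class `mech_result`: `k_shell` (N/m), `youngs_E`
#'   (Pa), `k_bend` (J), `k_bend_kBT`, `n_curves`.
#' @export
shell_mechanics <- function(curves, g, fit_range = NULL, T_K = 298) {
  if (inherits(curves, "force_curve")) curves <- list(curves)
  ks <- vapply(curves, shell_stiffness, numeric(1), fit_range = fit_range)
  k <- mean(ks)
  E <- youngs_modulus_from_stiffness(k, g)
  kb <- bending_modulus(g, E)
  structure(list(k_shell = k, k_shell_sd = stats::sd(ks),
                 youngs_E = E, k_bend = kb,
                 k_bend_kBT = in_kBT(kb, T_K), n_curves = length(curves)),
            class = "mech_result")
}

#' @export
print.mech_result <- function(x, ...) {
  cat("Thin-shell nanoindentation result\n")
  cat(sprintf("  k_shell  %.3g N/m (n = %d)\n", x$k_shell, x$n_curves))
  cat(sprintf("  E        %.3g GPa\n", x$youngs_E / 1e9))
  cat(sprintf("  K_bend   %.3g J (%.3g kBT)\n", x$k_bend, x$k_bend_kBT))
  invisible(x)
}
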