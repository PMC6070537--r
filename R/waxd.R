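#' Bragg angle of an orthorhombic reflection
#'
#' d-spacing from the orthorhombic metric
#' `1/d^2 = (h/a)^2 + (k/b)^2 + (l/c)^2` and the Bragg condition
#' `2 theta = 2 asin(lambda / 2d)` in degrees.  For the alpha-PLLA cell
#' the (110) and (200) planes are degenerate at d = 0.533 nm and give
#' the strongest powder peak near 16.7 degrees with Cu K-alpha.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer length-3 Miller indices, not all zero.
#' @param wavelength X-ray wavelength (nm); default Cu K-alpha 0.15406.
#' @return Two-theta in degrees.
#' @examples
#' bragg_two_theta(plla_alpha_cell(), c(1, 1, 0))
#' @export
bragg_two_theta <- function(cell, hkl, wavelength = 0.15406) {
  stopifnot(inherits(cell, "unit_cell"), length(hkl) == 3)
  if (all(hkl == 0)) stop("hkl must not be (0,0,0)")
  inv_d2 <- (hkl[1] / cell$a)^2 + (hkl[2] / cell$b)^2 + (hkl[3] / cell$c)^2
  d <- 1 / sqrt(inv_d2)
  s <- wavelength / (2 * d)
  if (s > 1) stop("no reflection: wavelength/2d exceeds 1")
  2 * asin(s) * 180 / pi
}
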