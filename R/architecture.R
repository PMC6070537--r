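#' Diblock copolymer block specification
#'
#' Describes the two blocks of a crystallizable amphiphilic diblock
#' copolymer (e.g. PLLA-b-PEG): the number-average molar mass of the
#' crystallizable (hydrophobic) and soluble (hydrophilic) block, the
#' repeat-unit masses, and the hydrophilic monomer size used in brush
#' scaling laws.
#'
#' Degrees of polymerization are derived as `floor(mn / m_repeat)`, so
#' e.g. a 5000 g/mol PEG block with a 44 g/mol repeat gives N = 113.
#'
#' @param mn_hydrophobic Molar mass of the crystallizable block (g/mol).
#' @param mn_hydrophilic Molar mass of the soluble brush-forming block (g/mol).
#' @param m_repeat_hydrophobic Repeat-unit molar mass of the crystallizable
#'   block (g/mol); 72 for L-lactide (LLA).
#' @param m_repeat_hydrophilic Repeat-unit molar mass of the soluble block
#'   (g/mol); 44 for ethylene glycol (EG).
#' @param a_monomer Hydrophilic monomer size (nm); 0.35 for EG in water.
#' @return An object of class `block_spec` with fields as above plus the
#'   derived degrees of polymerization `n_hydrophobic` and `n_hydrophilic`.
#' @examples
#' block_spec(6000, 5000)
#' @export
block_spec <- function(mn_hydrophobic, mn_hydrophilic,
                       m_repeat_hydrophobic = 72,
                       m_repeat_hydrophilic = 44,
                       a_monomer = 0.35) {
  stopifnot(mn_hydrophobic > 0, mn_hydrophilic > 0,
            m_repeat_hydrophobic > 0, m_repeat_hydrophilic > 0,
            a_monomer > 0)
  n_hb <- floor(mn_hydrophobic / m_repeat_hydrophobic)
  n_hl <- floor(mn_hydrophilic / m_repeat_hydrophilic)
  if (n_hb < 1 || n_hl < 1)
    stop("block molar mass below one repeat unit")
  structure(list(
    mn_hydrophobic = mn_hydrophobic,
    mn_hydrophilic = mn_hydrophilic,
    m_repeat_hydrophobic = m_repeat_hydrophobic,
    m_repeat_hydrophilic = m_repeat_hydrophilic,
    a_monomer = a_monomer,
    n_hydrophobic = n_hb,
    n_hydrophilic = n_hl
  ), class = "block_spec")
}

#' Orthorhombic crystal unit cell
#'
#' Lattice constants of an orthorhombic polymer unit cell, together with
#' the number of chains (stems) passing through one cell and the number
#' of monomers per c-axis repeat of the helix.  The default is the
#' alpha form of poly(L-lactide): a = 1.066 nm, b = 0.616 nm,
#' c = 2.888 nm, two chains per cell, 10_3 helix (10 monomers per
#' c repeat).
#'
#' @param a,b,c Lattice constants (nm).
#' @param chains_per_cell Number of chain stems per unit cell.
#' @param helix_monomers_per_c Monomers per c-axis repeat.
#' @return An object of class `unit_cell`.
#' @examples
#' plla_alpha_cell()
#' @export
unit_cell <- function(a, b, c, chains_per_cell = 2L,
                      helix_monomers_per_c = 10L) {
  stopifnot(a > 0, b > 0, c > 0, chains_per_cell >= 1,
            helix_monomers_per_c >= 1)
  structure(list(a = a, b = b, c = c,
                 chains_per_cell = as.integer(chains_per_cell),
                 helix_monomers_per_c = as.integer(helix_monomers_per_c)),
            class = "unit_cell")
}

#' @rdname unit_cell
#' @export
plla_alpha_cell <- function() unit_cell(1.066, 0.616, 2.888, 2L, 10L)

#' Crystalline stems and folds per chain
#'
#' For a lamellar crystal of thickness `t_crystal` grown from chains
#' whose crystallizable block has `N` monomers, each crystalline stem
#' traverses the lamella once and contains
#' `t_crystal / (c / helix_monomers_per_c)` monomers.  The chain then
#' folds `stems - 1` times.  Chain folding is integer-valued, so the
#' stem count is rounded to the nearest integer (minimum 1).
#'
#' @param spec A [block_spec()].
#' @param cell A [unit_cell()].
#' @param t_crystal Lamellar (crystal-layer) thickness in nm.
#' @return A list with integer `stems` and `folds` and the real-valued
#'   `monomers_per_stem`.
#' @examples
#' stems_and_folds(block_spec(6000, 5000), plla_alpha_cell(), 2.5)
#' @export
stems_and_folds <- function(spec, cell, t_crystal) {
  stopifnot(inherits(spec, "block_spec"), inherits(cell, "unit_cell"))
  if (t_crystal <= 0) stop("t_crystal must be positive")
  monomer_rise <- cell$c / cell$helix_monomers_per_c
  m_per_stem <- t_crystal / monomer_rise
  stems <- max(1L, as.integer(round(spec$n_hydrophobic / m_per_stem)))
  list(stems = stems, folds = stems - 1L, monomers_per_stem = m_per_stem)
}

#' Grafting density of the brush layer
#'
#' One soluble-block chain emerges from the fold surface per folded
#' crystallizable chain, i.e. per `stems` stem cross-sections of area
#' `a * b / chains_per_cell`.
#'
#' @param cell A [unit_cell()].
#' @param stems Integer number of stems per chain (>= 1).
#' @return Grafting density sigma in chains per nm^2.
#' @examples
#' grafting_density(plla_alpha_cell(), 10L)
#' @export
grafting_density <- function(cell, stems) {
  stopifnot(inherits(cell, "unit_cell"))
  if (stems < 1) stop("stems must be >= 1")
  area <- cell$a * cell$b / cell$chains_per_cell
  if (area <= 0) stop("unit cell basal area must be positive")
  1 / (stems * area)
}

#' Anchor spacing between adjacent grafted chains
#'
#' Square-lattice convention: D = sigma^(-1/2).  With the alpha-PLLA
#' cell and 10 stems this gives 1.81 nm.
#'
#' @param sigma Grafting density (chains/nm^2), positive.
#' @return Anchor distance D in nm.
#' @export
anchor_distance <- function(sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  sigma^(-0.5)
}

#' Flory radius of a swollen coil
#'
#' Good-solvent scaling `R_F = N^(3/5) * a`.
#'
#' @param n Degree of polymerization (>= 1).
#' @param a Monomer size (nm).
#' @return R_F in nm.
#' @examples
#' flory_radius(113, 0.35)
#' @export
flory_radius <- function(n, a) {
  stopifnot(n >= 1, a > 0)
  n^(3 / 5) * a
}

#' Alexander-de Gennes brush thickness
#'
#' `L = N * a^(5/3) * D^(-2/3)` for a chain of N monomers of size a
#' grafted at anchor spacing D.  Valid in the brush regime D < R_F;
#' at D = a the exponents cancel and L = N a (fully stretched).
#'
#' @param n Degree of polymerization.
#' @param a Monomer size (nm).
#' @param d Anchor spacing D (nm).
#' @return Brush thickness L in nm.
#' @examples
#' brush_thickness(113, 0.35, 1.81)
#' @export
brush_thickness <- function(n, a, d) {
  stopifnot(n >= 1, a > 0, d > 0)
  n * a^(5 / 3) * d^(-2 / 3)
}

#' Brush versus mushroom conformation
#'
#' A grafted layer is in the brush regime when the anchor spacing is
#' smaller than the Flory radius (D < R_F); the boundary D = R_F is
#' classified as mushroom.
#'
#' @param d Anchor spacing (nm).
#' @param rf Flory radius (nm).
#' @return `"brush"` or `"mushroom"`.
#' @export
brush_regime <- function(d, rf) {
  stopifnot(d > 0, rf > 0)
  if (d < rf) "brush" else "mushroom"
}

#' Layer thickness from grafting density, molar mass and density
#'
#' Mass balance for a dense layer of sigma chains/nm^2 of molar mass mn
#' and bulk density rho: `t = sigma * (mn / N_A) / rho`, with rho
#' converted from g/cm^3 to g/nm^3.
#'
#' @param sigma Grafting density (chains/nm^2).
#' @param mn Chain molar mass in the layer (g/mol).
#' @param density Layer density (g/cm^3).
#' @return Thickness in nm.
#' @export
layer_thickness_from_mass <- function(sigma, mn, density) {
  stopifnot(sigma > 0, mn > 0, density > 0)
  n_avogadro <- 6.02214076e23
  sigma * (mn / n_avogadro) / (density * 1e-21)
}

#' Crystal density from the unit cell
#'
#' rho = (monomers per cell) * m_repeat / (N_A * V_cell).  For the
#' alpha-PLLA cell (2 chains x 10 monomers of 72 g/mol in 1.896 nm^3)
#' this gives 1.261 g/cm^3.
#'
#' @param cell A [unit_cell()].
#' @param m_repeat Repeat-unit molar mass (g/mol).
#' @return Density in g/cm^3.
#' @export
cell_density <- function(cell, m_repeat = 72) {
  stopifnot(inherits(cell, "unit_cell"), m_repeat > 0)
  n_avogadro <- 6.02214076e23
  monomers <- cell$chains_per_cell * cell$helix_monomers_per_c
  vol_cm3 <- cell$a * cell$b * cell$c * 1e-21
  monomers * m_repeat / (n_avogadro * vol_cm3)
}

#' Full shell-architecture chain
#'
#' Runs the whole closed-form derivation: stems and folds from the
#' lamellar thickness, grafting density, anchor spacing, Flory radius,
#' brush thickness and regime, and the mass-balance layer thicknesses.
#'
#' @param spec A [block_spec()].
#' @param cell A [unit_cell()].
#' @param t_crystal Crystal-layer thickness (nm).
#' @param density_hydrophobic Crystal density (g/cm^3); default from the
#'   unit cell via [cell_density()].
#' @param density_hydrophilic Amorphous density of the soluble block
#'   (g/cm^3); default 1.12 (amorphous PEG).
#' @return An object of class `crystal_architecture`: a list with
#'   `stems`, `folds`, `sigma`, `anchor_distance_D`, `flory_radius_RF`,
#'   `brush_thickness_L`, `regime`, `t_crystal`, `t_brush_dry`.
#' @examples
#' crystal_architecture(block_spec(6000, 5000), plla_alpha_cell(), 2.5)
#' @export
crystal_architecture <- function(spec, cell, t_crystal,
                                 density_hydrophobic = cell_density(cell, spec$m_repeat_hydrophobic),
                                 density_hydrophilic = 1.12) {
  sf <- stems_and_folds(spec, cell, t_crystal)
  sigma <- grafting_density(cell, sf$stems)
  d <- anchor_distance(sigma)
  rf <- flory_radius(spec$n_hydrophilic, spec$a_monomer)
  l <- brush_thickness(spec$n_hydrophilic, spec$a_monomer, d)
  structure(list(
    stems_per_chain = sf$stems,
    folds_per_chain = sf$folds,
    monomers_per_stem = sf$monomers_per_stem,
    sigma = sigma,
    anchor_distance_D = d,
    flory_radius_RF = rf,
    brush_thickness_L = l,
    regime = brush_regime(d, rf),
    t_crystal = layer_thickness_from_mass(sigma, spec$mn_hydrophobic,
                                          density_hydrophobic),
    t_brush_dry = layer_thickness_from_mass(sigma, spec$mn_hydrophilic,
                                            density_hydrophilic)
  ), class = "crystal_architecture")
}

#' @export
print.crystal_architecture <- function(x, ...) {
  cat("Crystalsome shell architecture\n")
  cat(sprintf("  stems per chain        %d (%.2f monomers/stem)\n",
              x$stems_per_chain, x$monomers_per_stem))
  cat(sprintf("  folds per chain        %d\n", x$folds_per_chain))
  cat(sprintf("  grafting density sigma %.4f chains/nm^2\n", x$sigma))
  cat(sprintf("  anchor distance D      %.3f nm\n", x$anchor_distance_D))
  cat(sprintf("  Flory radius R_F       %.3f nm\n", x$flory_radius_RF))
  cat(sprintf("  brush thickness L      %.2f nm (%s regime)\n",
              x$brush_thickness_L, x$regime))
  cat(sprintf("  crystal layer (mass balance) %.2f nm\n", x$t_crystal))
  cat(sprintf("  dry brush layer (mass balance) %.2f nm\n", x$t_brush_dry))
  invisible(x)
}
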