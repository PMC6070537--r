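# crystalsome

Analysis toolkit for **block-copolymer crystalsomes** (BCCs): hollow
nanoparticles whose shell is a chain-folded polymer single crystal
grown at the curved oil/water interface of an emulsion droplet.  For a
PLLA-*b*-PEG diblock, crystallization of the PLLA block at the
interface folds each chain into a thin lamella and simultaneously
tethers one PEG chain per folded PLLA chain into the water phase, so
the PEG brush grafting density is set by crystallography.  The package
is aimed at polymer-physics and nanomedicine groups who need the
quantitative chain from unit cell to brush architecture, shell
mechanics, confined-nucleation simulation and blood-circulation
pharmacokinetics in one tested place.

## What it computes

**Shell architecture** (`crystal_architecture()` and friends).  From
the block molar masses, the orthorhombic alpha-PLLA cell
(a = 1.066 nm, b = 0.616 nm, c = 2.888 nm, 2 chains/cell, 10_3 helix)
and the lamellar thickness *t*:

- stems per chain `round(N_PLLA / (t / (c/10)))`, folds = stems − 1
- grafting density σ = 1/(stems · ab/2), anchor spacing D = σ^(−1/2)
- Flory radius R_F = N^(3/5) a and Alexander–de Gennes brush height
  L = N a^(5/3) D^(−2/3), with brush/mushroom classification
- mass-balance layer thicknesses, DSC crystallinity against the
  91 J g⁻¹ reference, and powder-diffraction peak positions
  (`bragg_two_theta()`)

**Confined nucleation** (`mc_config()`, `build_system()`, `mc_run()`,
`detect_crystalline_bonds()`, `cluster_nuclei()`, `mc_replicates()`).
A coarse-grained lattice Monte-Carlo model of A₃₈B₂₈ diblocks at a
spherical oil/water interface: 26-neighbour cubic lattice,
micro-relaxation moves with sliding diffusion, Metropolis sampling at
k_BT/E_c = 3.6, crystalline-bond detection, nucleus clustering, and
replicate-averaged radial profiles of nucleus size R_nucleus(d) and
radial orientation order.

**Shell mechanics** (`shell_stiffness()`,
`youngs_modulus_from_stiffness()`, `bending_modulus()`).  Reissner
thin-shell point-load relation k = 4Eh²/(R√(3(1−ν²))) applied to AFM
force–deformation curves, plus the plate bending rigidity
K = Eh³/(12(1−ν²)) and its k_BT conversion.

**Circulation pharmacokinetics** (`fit_one_compartment()`,
`retention_at()`, `biodistribution_summary()`,
`crystallinity_halflife_table()`).  Per-animal log-linear (or
nonlinear) fits of C(t) = C₀e^(−kt), group half-life summaries,
retention, release fractions, organ-panel tables and the
crystallinity–half-life rank correlation.

**Synthetic data** (`gen_force_curve()`, `gen_thermogram()`,
`gen_circulation()`, `gen_organ_panel()`).  Seeded generators with
embedded ground truth for every input the pipeline consumes, so all
stages are testable without downloads.

## Worked example

```r
library(crystalsome)

arch <- crystal_architecture(block_spec(6000, 5000), plla_alpha_cell(),
                             t_crystal = 2.5)
arch
#> Crystalsome shell architecture
#>   stems per chain        10 (8.66 monomers/stem)
#>   folds per chain        9
#>   grafting density sigma 0.3046 chains/nm^2
#>   anchor distance D      1.812 nm
#>   Flory radius R_F       5.969 nm
#>   brush thickness L      13.22 nm (brush regime)
#>   crystal layer (mass balance) 2.41 nm
#>   dry brush layer (mass balance) 2.26 nm
```

Each PLLA chain folds 9 times into 10 stems of ~8.7 monomers, which
pins one PEG chain per 3.28 nm² (σ ≈ 0.30 nm⁻²).  The anchor spacing
1.81 nm is far below the PEG Flory radius 5.97 nm, so the PEG layer is
a stretched brush 13.2 nm high rather than a mushroom layer.

```r
g <- shell_geometry(radius_R = 90, thickness_h = 4.5, poisson_nu = 0.33)
k <- stiffness_from_modulus(11.5e9, g)          # 6.33 N/m
bending_modulus(g, 11.5e9)                      # 9.80e-17 J
in_kBT(bending_modulus(g, 11.5e9))              # 2.38e4 at 298 K

fit <- fit_one_compartment(gen_circulation(list(half_life_h = 24.2,
                                                noise_cv = 0), seed = 1))
fit$half_life_h                                 # 24.2
retention_at(fit, c(24, 72, 96))                # 50.29  12.72  6.39 (%)
```

A 4.5 nm crystalline shell of modulus 11.5 GPa has a bending rigidity
of ~10⁻¹⁶ J — orders of magnitude stiffer than a fluid polymersome
membrane — and a mono-exponential clearance with a 24.2 h half-life
retains ~6% of the dose in plasma at 96 h.

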