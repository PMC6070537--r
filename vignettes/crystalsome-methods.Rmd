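---
title: "Models and methods behind crystalsome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crystalsome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystalsome)
```

# The system

A block-copolymer crystalsome (BCC) is a hollow, vesicle-like
nanoparticle whose shell is a chain-folded polymer single crystal grown
at the curved oil/water interface of an emulsion droplet.  For a
PLLA-b-PEG diblock (M~n~ = 6000 / 5000 g mol^-1^), the crystallizable
PLLA block folds into a thin lamella that wraps the droplet while every
fold ejects one PEG chain into the water phase, producing a PEG brush
whose grafting density is dictated by crystallography rather than by
grafting chemistry.  The package implements the quantitative chain that
connects: (i) the crystal unit cell and lamellar thickness to the brush
architecture; (ii) a lattice Monte-Carlo model of how the confined
crystal nucleates; (iii) AFM nanoindentation to shell elasticity;
(iv) blood-circulation fluorescence series to pharmacokinetic
parameters; together with seeded generators of synthetic data for every
input so that the whole pipeline is testable from code alone.

# Shell architecture from crystallography and brush scaling

The PLLA alpha form is orthorhombic, a = 1.066 nm, b = 0.616 nm,
c = 2.888 nm, two chains per cell, with the chain in a 10~3~ helix (10
monomers per c repeat).  A lamella of thickness $t$ therefore contains
$t/(c/10)$ monomers per stem, and a block of $N_{PLLA} =
\lfloor M_n/72 \rfloor$ monomers forms

$$n_{stem} = \mathrm{round}\!\left(\frac{N_{PLLA}}{t\,/\,(c/10)}\right),
\qquad n_{fold} = n_{stem} - 1 .$$

Rounding to the nearest integer reflects that folding is
integer-valued; with $t = 2.5$ nm this gives 10 stems and 9 folds.  One
PEG chain leaves the fold surface per chain, i.e. per $n_{stem}$ stem
cross-sections of area $ab/2$, so
$\sigma = 1/(n_{stem}\, ab/2)$ and the anchor spacing follows the
square-lattice convention $D = \sigma^{-1/2}$.  We use the square-root
convention (rather than a hexagonal-packing prefactor) because the fold
surface of the orthorhombic lamella is itself a rectangular lattice of
stems; with $\sigma = 0.3046$ nm^-2^ it gives $D = 1.81$ nm.  We keep
the exact $\sigma$ rather than a pre-rounded 0.3 through this chain.

The PEG conformation is classified by comparing $D$ with the Flory
radius $R_F = N^{3/5} a$ ($a = 0.35$ nm, $N = \lfloor 5000/44 \rfloor
= 113$): brush if $D < R_F$, mushroom otherwise, with the boundary
$D = R_F$ classified as mushroom.  In the brush regime the
Alexander-de Gennes height is $L = N a^{5/3} D^{-2/3}$.  Layer
thicknesses also follow from mass balance,
$t = \sigma m_n / (N_A \rho)$, with the PLLA crystal density computed
from the unit cell itself (1.261 g cm^-3^) and amorphous PEG taken as
1.12 g cm^-3^; both densities are arguments, since different density
choices shift these estimates by a few percent.

DSC crystallinity integrates the baseline-subtracted melting endotherm
over a user-chosen window, converts heat flow to enthalpy through the
heating rate, and divides by the 91 J g^-1^ reference for fully
crystalline alpha-PLLA.  The baseline is the straight line through the
trace at the window endpoints, which makes the result exactly invariant
to adding any linear function of temperature to the signal.  Powder
peak positions come from the orthorhombic metric
$1/d^2 = (h/a)^2 + (k/b)^2 + (l/c)^2$ and Bragg's law; peak
intensities and full patterns are out of scope.

# Lattice Monte-Carlo model of confined nucleation

Chains are A~38~B~28~ diblocks (A = PEG, B = PLLA, N = 66) on a simple
cubic lattice with bonds along the 26 axial, face-diagonal and
body-diagonal directions, single occupancy, periodic boundaries.
Vacant sites are solvent, typed by a fixed spherical region map: oil
inside the droplet, water outside.  The interface itself does not
deform.  Three energies, all expressed in units of the rigidity
penalty E~c~:

* **E~c~** per non-collinear pair of consecutive bonds (chain
  stiffness, the driving force for stem formation);
* **E~p~** gained per pair of parallel, non-bonded, adjacent B-B bonds
  (crystalline packing);
* **B** per unlike contact (B-water, A-oil, A-B), which holds the
  amphiphile at the interface.

The reduced temperature is fixed at $k_BT/E_c = 3.6$.  Moves are
micro-relaxations: a random monomer attempts to step to a vacant
neighbour site; if the step would break the chain, the neighbouring
monomers slide along the chain contour to restore connectivity
(reptation-like sliding diffusion).  Metropolis acceptance uses an
incremental energy difference computed over a *stable term universe*
(angle terms indexed by monomer, packing terms by bond pairs, contact
terms by site pairs), which makes the incremental bookkeeping equal to
a full recomputation to machine precision -- a property the test suite
asserts against an independent brute-force oracle.

Only the reduced temperature, chain architecture, chain number and box
of the original study are public; the packing and mixing energies are
not.  We expose them as configuration and default to
$E_p/E_c = 2.5$, $B/E_c = 0.5$: at 3.6 reduced temperature the
parallel attraction must exceed roughly 1.5 E~c~ for any nucleation to
occur at the densities reached in the brush layer, while above roughly
3 E~c~ growth is immediate and spinodal-like; 2.5 produces the
heterogeneous scenario the study describes -- several small nuclei
appear just inside the interface within a fraction of the chain
relaxation time, grow, merge or redissolve, and leave a single crystal
after a few tens of relaxation times.  The mixing energy mainly needs
to be large enough that chains stay anchored on simulation timescales.

A B-B bond is *crystalline* when at least `min_parallel = 5` parallel
B-B bonds sit on adjacent lattice lines (bonds sharing a monomer do not
count).  The threshold is not printed in the source study; 5 is large
enough that isolated straight chains and transient pair contacts do not
register, and small enough that a 3x3 stem bundle is fully crystalline.
Crystalline bonds are clustered by site adjacency into nuclei; each
nucleus is summarized by its bond count $s$, the radius
$R_{nucleus} = (3 s v_{bond}/4\pi)^{1/3}$ of the sphere with the
equivalent crystalline volume (one lattice-site volume per bond), the
distance $d$ of its centre of mass from the droplet centre, and its
radial orientation order $\langle P_2(\hat b \cdot \hat r)\rangle$,
which is 1 for stems along the local radius, -0.5 for tangential stems
and 0 for isotropic ones.  Profiles of mean nucleus size and
orientation versus $d$ are averaged over independent replicates, each
seeded as master seed + replicate index.

For nucleus *counts* we exclude clusters below 10 bonds and below 2%
of the total crystalline-bond count at that time: in the
sub-nucleation regime the model continuously creates and destroys
clusters of up to about 7 bonds, and during late-stage coarsening the
growth front of the dominant crystal sheds transient fragments that
flicker in and out of cluster adjacency, reaching about 1.5% of the
crystal, while genuine secondary crystals hold at least several
percent; the absolute threshold removes the sub-critical
fluctuations and the relative one sits in the clear gap between the
fragment and crystal size populations at any system scale.  The standard trajectory protocol pre-relaxes the
freshly built brush for 500 sweeps with the packing attraction
switched off before the quench, so that nucleation starts from an
equilibrated interfacial chain distribution rather than from the
construction walk.  Times are recorded in sweeps (one
attempted move per monomer); `relax_and_measure_tau()` converts to
units of the B-block relaxation time $\tau$, defined as the 1/e decay
lag of the B-block end-to-end autocorrelation with the packing
attraction switched off.  $\tau$ depends on the model parameters and
density, so it is measured per configuration rather than hard-coded.

**Geometry.**  The printed full-scale geometry (box
100 x 100 x 99, 3000 chains, 24 replicates) places the interface at a
distance from the droplet centre that cannot be reconciled with the box
dimensions, and the lattice-unit-to-nm conversion is not stated; the
droplet radius is therefore an independent parameter here.  The package
default is a desk-scale droplet of radius 20 sites with 300 chains and
8 replicates, which runs the full nucleation-to-single-crystal
trajectory in minutes of CPU time; `mc_fullscale_config()` selects the
full-scale geometry when that cost is acceptable.  At desk scale the
B-block length (28) is a substantial fraction of the droplet radius, so
the sub-interface nucleation offset is relatively larger than in the
full-scale study, and the late-stage crystal wraps the droplet (pulling
its centre of mass toward the droplet centre, which is why radial
profiles are most informative during the growth phase).  A radius-20
droplet also cannot volumetrically hold the B blocks of more than a few
hundred chains (the interior volume fraction is $84\sigma/R$), capping
the grafting density several-fold below the experimental value; the
brush is therefore only weakly stretched and the radial orientation
preference of growing nuclei, while present, is much weaker than the
full-scale study reports.  The properties preserved across scales and
asserted in the tests are: nucleation strictly inside the interface
(positive offset), a positive -- if weak -- radial orientation of
growth-zone nuclei with no preferred orientation at the interface
itself, and coarsening to a single crystal.

# Thin-shell nanoindentation mechanics

For a point-loaded thin spherical shell the Reissner stiffness is

$$k_{shell} = \frac{4 E h^2}{R \sqrt{3 (1-\nu^2)}},$$

inverted to obtain Young's modulus from the least-squares slope of the
linear deformation regime of an AFM force-deformation curve (default
fit range: 10-80% of the maximum deformation).  The wall bending
modulus is the plate rigidity $K = E h^3 / 12(1-\nu^2)$, also reported
in units of $k_BT$ at 298 K.  Poisson's ratio defaults to 0.33, the
value consistent with the published dry-state chain E = 11.5 GPa,
h = 4.5 nm, K = 9.8 x 10^-17^ J.  The wet-state bending modulus of the
source study cannot be reproduced from any printed (E, h, nu)
combination -- it presumably uses an effective solvated thickness
defined in unpublished supplementary material -- so the package exposes
thickness as an input rather than asserting a wet-state value.
Published tabulated reference values for that shell also disagree with
the in-text figure by roughly an order of magnitude in $k_BT$ units;
the conversion here follows the in-text chain.

# One-compartment pharmacokinetics

Plasma fluorescence after an i.v. bolus is modelled as
$C(t) = C_0 e^{-kt}$ with half-life $t_{1/2} = \ln 2 / k$.  (The
source study prints the exponent with a spurious $t_{1/2}$ subscript;
the reported half-lives are consistent with the standard form used
here.)  The default fit is unweighted log-linear least squares of
$\ln C$ on $t$ per animal -- the standard estimator for mono-exponential
bolus data -- with a Levenberg-Marquardt fit on the untransformed scale
available as an option; the two agree exactly on noiseless data.
Intensities are normalized to the first (2-minute) draw, non-positive
values are excluded from log fits with a warning, and group summaries
are the mean and s.d. of per-animal half-lives.  Retention at time
$t$ is $100 e^{-kt}$ under the model; because empirical retentions can
exceed the mono-exponential prediction at late times, a data-based
variant interpolates the normalized intensities instead.
Biodistribution panels are summarized two ways: control-subtracted
signal per gram of tissue (negatives clipped to zero, clip count
reported) and each organ's share of the total signal at a time point
(shares sum to 1).  The crystallinity-half-life relationship across
crystallization-time groups is summarized by the Spearman rank
correlation, which is undefined (and flagged) when either variable is
constant.

# Synthetic data generators

Each generator embeds its ground truth in the returned object so the
paired analysis can be tested as an estimator:

* **Force curves**: zero-force approach then a linear contact regime of
  the requested stiffness, with additive Gaussian force noise (AFM
  deflection noise is well modelled as additive).
* **Thermograms**: linear baseline plus two Gaussian endotherms at
  49.0 and 138.9 deg C with requested areas in J g^-1^, sampled at
  10 deg C min^-1^.
* **Circulation series**: $C_0 e^{-kt}$ at the standard sampling grid
  (2 min-96 h) times lognormal noise -- plate-reader intensities are
  positive and right-skewed, so noise is multiplicative and the
  generator never emits negative values.  Cohort defaults mirror the
  studied groups: half-lives 0.80, 3.3, 24.2 h with 4, 3, 5 animals.
* **Organ panels**: dose x enrichment-weight x lognormal noise plus a
  control baseline, masses from fixed realistic murine ranges, with
  liver/spleen-dominant default weights (reticuloendothelial
  clearance).

The generators reproduce the statistical *structure* the analyses
assume -- mono-exponential decay, linear contact mechanics, Gaussian
endotherms -- not the full complexity of real data (no drift, no
heteroscedastic plateaus, no inter-animal rate variability beyond the
noise model).  Passing recovery tests therefore demonstrates estimator
correctness under the stated model, not robustness to model violation.

# Numerical choices and problem sizes

* DSC integration uses the trapezoidal rule on the native temperature
  grid with endpoint interpolation; generator grids are 0.1 deg C.
* The half-life estimator bias check uses 200 cohorts of 5 animals at
  10% lognormal noise; the mechanics recovery check uses 14 replicate
  curves at 5% noise, mirroring the replicate counts of the source
  experiments.
* MC ensemble checks use the desk-scale geometry above; energy-oracle
  equivalence is asserted on boxes up to 12^3^, where the brute-force
  O(bonds^2^) reference is affordable.
* All stochastic stages consume a single master seed; replicate seeds
  are derived by fixed increments and recorded in provenance sidecars.

# Known limitations

* The lattice model has a rigid interface; droplet deformation,
  hydrodynamics and the emulsification stage are not modelled.
* Sliding-diffusion moves satisfy detailed balance only approximately
  for long slides; the test suite checks single-chain statistics
  against exhaustive enumeration to bound the effect at the scale that
  matters for conformational sampling.
* Only peak *positions* of the powder pattern are computed.
* The one-compartment model cannot represent the late-time retention
  excess seen in real circulation data; the data-based retention
  variant exists for exactly that case.
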