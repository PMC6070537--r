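#' Lattice Monte-Carlo configuration
#'
#' Parameters of the coarse-grained lattice model of diblock-copolymer
#' crystallization at a spherical liquid-liquid interface.  Chains are
#' A-B diblocks (A = soluble brush block, B = crystallizable block) on
#' a simple cubic lattice with 26-neighbour bonds; vacant sites are
#' solvent, oil inside the droplet and water outside.  Energies in
#' units of the chain-rigidity penalty E_c: the reduced temperature is
#' kT/E_c, `ep_over_ec` is the parallel-packing attraction between
#' crystallizable bonds, and `b_over_ec` the unlike-contact mixing
#' energy (B-water, A-oil, A-B).
#'
#' The default geometry is a desk-scale droplet (radius 20 sites,
#' 300 chains, 8 replicates); [mc_fullscale_config()] gives the full-scale
#' geometry (box 100 x 100 x 99, 3000 chains, 24 replicates).
#'
#' @param box Integer lattice dimensions, length 3, each >= 4.
#' @param droplet_radius Droplet radius in lattice units.
#' @param n_chains Number of chains.
#' @param block_lengths `c(n_A, n_B)`; default `c(38, 28)` (chain
#'   length N = 66).
#' @param reduced_temperature kT/E_c; default 3.6.
#' @param ep_over_ec Parallel attraction E_p/E_c; default 2.5, chosen
#'   so that at kT/E_c = 3.6 the confined melt nucleates heterogeneously
#'   near the interface and coarsens to a single crystal within tens of
#'   relaxation times (the regime the experiment operates in).  Below
#'   about 1.5 no nucleation occurs at this temperature; above about 3
#'   growth is immediate and near-spinodal.
#' @param b_over_ec Mixing energy B/E_c; default 0.5.
#' @param min_parallel Crystalline-bond threshold: a B-B bond is
#'   crystalline when it has at least this many parallel neighbouring
#'   B-B bonds; default 5.
#' @param n_replicates Independent replicate runs; default 8.
#' @param seed Master seed; replicate r uses `seed + r - 1`.
#' @param droplet_center Lattice coordinates; default box centre.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(box = c(48L, 48L, 48L), droplet_radius = 20,
                      n_chains = 300L, block_lengths = c(38L, 28L),
                      reduced_temperature = 3.6, ep_over_ec = 2.5,
                      b_over_ec = 0.5, min_parallel = 5L,
                      n_replicates = 8L, seed = 1L,
                      droplet_center = NULL) {
  box <- as.integer(box)
  stopifnot(length(box) == 3, all(box >= 4), droplet_radius > 0,
            n_chains >= 1, length(block_lengths) == 2,
            all(block_lengths >= 1), reduced_temperature > 0,
            min_parallel >= 1, n_replicates >= 1)
  if (is.null(droplet_center)) droplet_center <- box / 2
  structure(list(box = box, droplet_radius = droplet_radius,
                 droplet_center = as.numeric(droplet_center),
                 n_chains = as.integer(n_chains),
                 n_a = as.integer(block_lengths[1]),
                 n_b = as.integer(block_lengths[2]),
                 reduced_temperature = reduced_temperature,
                 ep_over_ec = ep_over_ec, b_over_ec = b_over_ec,
                 min_parallel = as.integer(min_parallel),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "mc_config")
}

#' @rdname mc_config
#' @param ... Overrides passed to [mc_config()].
#' @export
mc_fullscale_config <- function(...) {
  args <- modifyList(list(box = c(100L, 100L, 99L), droplet_radius = 48,
                          n_chains = 3000L, n_replicates = 24L), list(...))
  do.call(mc_config, args)
}

#' Build the initial chain system at the interface
#'
#' Places each chain with its block junction just inside the spherical
#' interface, the crystallizable B block as a random walk inside the
#' droplet (oil side) and the A block as a random walk outside (water
#' side), with no double occupancy.  Errors if the requested chain
#' count cannot be packed on the interface shell, reporting how many
#' chains were achievable.
#'
#' @param cfg An [mc_config()].
#' @param seed Seed for placement randomness (default `cfg$seed`).
#' @return An object of class `chain_system`: list with the 0-based
#'   position matrix `pos` (n_monomers x 3) and `cfg`.
#' @export
build_system <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "mc_config"))
  set.seed(seed)
  pos <- mc_build_cpp(cfg$box, cfg$droplet_center, cfg$droplet_radius,
                      cfg$n_chains, cfg$n_a, cfg$n_b, 500L)
  structure(list(pos = pos, cfg = cfg), class = "chain_system")
}

#' @export
print.chain_system <- function(x, ...) {
  cat(sprintf("chain_system: %d chains of A%d-B%d (%d monomers) in %s box, droplet radius %g\n",
              x$cfg$n_chains, x$cfg$n_a, x$cfg$n_b, nrow(x$pos),
              paste(x$cfg$box, collapse = "x"), x$cfg$droplet_radius))
  invisible(x)
}

#' Total lattice energy of a chain system
#'
#' Full recomputation of the three energy-term counts (non-collinear
#' consecutive bond pairs, parallel adjacent B-bond pairs,
#' unlike contacts) and the total energy in units of E_c.
#'
#' @param sys A [build_system()] result.
#' @return List with `noncollinear`, `parallel_pairs`,
#'   `unlike_contacts` and `energy` (E/E_c).
#' @export
system_energy <- function(sys) {
  stopifnot(inherits(sys, "chain_system"))
  cfg <- sys$cfg
  ct <- mc_energy_counts_cpp(sys$pos, cfg$box, cfg$droplet_center,
                             cfg$droplet_radius, cfg$n_a, cfg$n_b,
                             cfg$n_chains)
  list(noncollinear = ct[["noncollinear"]],
       parallel_pairs = ct[["parallel_pairs"]],
       unlike_contacts = ct[["unlike_contacts"]],
       energy = ct[["noncollinear"]] +
         cfg$b_over_ec * ct[["unlike_contacts"]] -
         cfg$ep_over_ec * ct[["parallel_pairs"]])
}

#' Run Monte-Carlo sweeps
#'
#' One sweep is one attempted micro-relaxation move per monomer on
#' average.  Moves preserve chain connectivity and excluded volume;
#' Metropolis acceptance `min(1, exp(-dE / (kT/E_c)))` with incremental
#' energy bookkeeping.  The accumulated energy change is returned so
#' incremental accounting can be checked against [system_energy()].
#'
#' @param sys A `chain_system`.
#' @param sweeps Number of sweeps (may be fractional).
#' @param ep_over_ec,b_over_ec Optional overrides of the config values
#'   (e.g. `ep_over_ec = 0` to disable crystallization during
#'   relaxation).
#' @return The updated `chain_system`, with attributes `delta_e`
#'   (accumulated energy change, E_c units), `attempted`, `accepted`.
#' @export
mc_run <- function(sys, sweeps, ep_over_ec = sys$cfg$ep_over_ec,
                   b_over_ec = sys$cfg$b_over_ec) {
  stopifnot(inherits(sys, "chain_system"), sweeps >= 0)
  cfg <- sys$cfg
  res <- mc_run_cpp(sys$pos, cfg$box, cfg$droplet_center,
                    cfg$droplet_radius, cfg$n_a, cfg$n_b, cfg$n_chains,
                    sweeps, cfg$reduced_temperature, ep_over_ec, b_over_ec)
  out <- structure(list(pos = res$pos, cfg = cfg), class = "chain_system")
  attr(out, "delta_e") <- res$delta_e
  attr(out, "attempted") <- res$attempted
  attr(out, "accepted") <- res$accepted
  out
}

#' Detect crystalline bonds
#'
#' A B-B chain bond is crystalline when it has at least `min_parallel`
#' parallel neighbouring B-B bonds (same lattice direction, endpoints
#' shifted by one 26-neighbourhood offset; bonds sharing a monomer are
#' not counted).  Crystalline bonds are grouped into nuclei by
#' connected components under site adjacency.  Deterministic given the
#' configuration.
#'
#' @param sys A `chain_system`.
#' @param min_parallel Threshold; default from the config.
#' @return A data.frame of class `crystal_bonds`: one row per
#'   crystalline bond with first-monomer id (0-based), endpoint
#'   coordinates, bond direction, parallel-neighbour count and cluster
#'   id.
#' @export
detect_crystalline_bonds <- function(sys, min_parallel = sys$cfg$min_parallel) {
  stopifnot(inherits(sys, "chain_system"), min_parallel >= 1)
  cfg <- sys$cfg
  b <- mc_crystal_bonds_cpp(sys$pos, cfg$box, cfg$droplet_center,
                            cfg$droplet_radius, cfg$n_a, cfg$n_b,
                            cfg$n_chains, as.integer(min_parallel))
  class(b) <- c("crystal_bonds", "data.frame")
  attr(b, "cfg") <- cfg
  b
}

#' Second Legendre polynomial
#'
#' `P2(x) = (3 x^2 - 1) / 2`, the nematic orientation order parameter
#' kernel; its range on unit-vector cosines is -0.5 to 1 and its mean
#' under isotropic directions is 0.
#'
#' @param x Cosine values.
#' @return P2(x).
#' @export
p2_legendre <- function(x) (3 * x^2 - 1) / 2

#' Cluster crystalline bonds into nucleus records
#'
#' Computes, per connected cluster of crystalline bonds: `size` (bond
#' count), `d_cm` (distance of the cluster centre of mass from the
#' droplet centre, from minimal-image bond midpoints),
#' `R_nucleus = (3 size v_bond / 4 pi)^(1/3)` with `v_bond` one
#' lattice-site volume per bond, and `orientation`, the mean
#' P2(cos theta) between bond directions and the radial unit vector at
#' the centre of mass (range -0.5 to 1; 0 for isotropic bonds).
#'
#' @param bonds A [detect_crystalline_bonds()] result.
#' @param v_bond Per-bond volume calibration (lattice site volumes).
#' @return Data.frame with one row per nucleus: `cluster`, `size`,
#'   `R_nucleus`, `d_cm`, `orientation`.
#' @export
cluster_nuclei <- function(bonds, v_bond = 1) {
  stopifnot(inherits(bonds, "crystal_bonds"), v_bond > 0)
  cfg <- attr(bonds, "cfg")
  if (nrow(bonds) == 0)
    return(data.frame(cluster = integer(), size = integer(),
                      R_nucleus = numeric(), d_cm = numeric(),
                      orientation = numeric()))
  box <- cfg$box; ctr <- cfg$droplet_center
  # minimal-image displacement of bond midpoints from the droplet centre
  mid <- cbind(bonds$x + bonds$dx / 2, bonds$y + bonds$dy / 2,
               bonds$z + bonds$dz / 2)
  disp <- sweep(mid, 2, ctr)
  for (k in 1:3) disp[, k] <- disp[, k] - box[k] * round(disp[, k] / box[k])
  dirn <- cbind(bonds$dx, bonds$dy, bonds$dz)
  dirn <- dirn / sqrt(rowSums(dirn^2))
  out <- lapply(sort(unique(bonds$cluster)), function(cl) {
    i <- bonds$cluster == cl
    cm <- colMeans(disp[i, , drop = FALSE])
    d <- sqrt(sum(cm^2))
    rhat <- if (d > 1e-9) cm / d else c(0, 0, 1)
    ori <- mean(p2_legendre(as.matrix(dirn[i, , drop = FALSE]) %*% rhat))
    data.frame(cluster = cl, size = sum(i),
               R_nucleus = (3 * sum(i) * v_bond / (4 * pi))^(1 / 3),
               d_cm = d, orientation = ori)
  })
  do.call(rbind, out)
}

#' Radial profile of nucleus size and orientation
#'
#' Bins nucleus records by centre-of-mass distance d and averages
#' R_nucleus and orientation per bin.
#'
#' @param nuclei Data.frame from [cluster_nuclei()] (possibly several
#'   replicates row-bound together).
#' @param bin_edges Radial bin edges (lattice units), covering
#'   0 to droplet_radius + margin.
#' @return Data.frame: `d_mid`, `mean_R_nucleus`, `mean_orientation`,
#'   `n_samples` per bin (zero rows give NA means and n = 0).
#' @export
radial_profile <- function(nuclei, bin_edges) {
  stopifnot(length(bin_edges) >= 2, all(diff(bin_edges) > 0))
  mids <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  idx <- findInterval(nuclei$d_cm, bin_edges, rightmost.closed = TRUE)
  out <- data.frame(d_mid = mids, mean_R_nucleus = NA_real_,
                    mean_orientation = NA_real_, n_samples = 0L)
  for (b in seq_along(mids)) {
    i <- idx == b
    if (any(i)) {
      out$mean_R_nucleus[b] <- mean(nuclei$R_nucleus[i])
      out$mean_orientation[b] <- mean(nuclei$orientation[i])
      out$n_samples[b] <- sum(i)
    }
  }
  out
}

#' Run one replicate and record nucleus statistics over time
#'
#' Builds a system, optionally pre-relaxes it with the parallel
#' attraction switched off, then runs to each requested sweep count and
#' records the nucleus records and summary counts.  Nuclei smaller than
#' `min_size` bonds are treated as sub-critical fluctuations and are
#' excluded from the nucleus count (they still enter the radial
#' profiles).
#'
#' @param cfg An [mc_config()].
#' @param record_sweeps Increasing vector of sweep counts to record at.
#' @param seed Replicate seed; default `cfg$seed`.
#' @param relax_sweeps Athermal (E_p = 0) pre-relaxation sweeps.
#' @param min_size Absolute minimum bond count for a cluster to count
#'   as a nucleus; default 10 (pre-nucleation fluctuations reach ~7
#'   bonds at the default parameters).
#' @param min_frac Relative minimum: a counted nucleus must also hold
#'   at least this fraction of all crystalline bonds at that time
#'   (default 0.02).  During late-stage coarsening the growth front
#'   sheds transient fragments of up to ~1.5% of the crystal, while
#'   genuine secondary crystals hold >=5%; the relative threshold sits
#'   in that gap and scales with the system.
#' @return List of class `mc_trajectory`: `times` (sweeps), `nuclei`
#'   (list of per-time nucleus data.frames), `summary` data.frame
#'   (`sweeps`, `n_nuclei`, `n_bonds`, `largest`, `mean_size`), and the
#'   final `system`.
#' @export
mc_trajectory <- function(cfg, record_sweeps, seed = cfg$seed,
                          relax_sweeps = 0, min_size = 10,
                          min_frac = 0.02) {
  stopifnot(inherits(cfg, "mc_config"), all(diff(record_sweeps) > 0))
  sys <- build_system(cfg, seed = seed)
  if (relax_sweeps > 0) sys <- mc_run(sys, relax_sweeps, ep_over_ec = 0)
  prev <- 0
  nuclei <- list()
  summ <- list()
  for (i in seq_along(record_sweeps)) {
    sys <- mc_run(sys, record_sweeps[i] - prev)
    prev <- record_sweeps[i]
    bonds <- detect_crystalline_bonds(sys)
    nuc <- cluster_nuclei(bonds)
    nuclei[[i]] <- nuc
    total <- if (nrow(nuc)) sum(nuc$size) else 0L
    thr <- max(min_size, min_frac * total)
    big <- nuc[nuc$size >= thr, , drop = FALSE]
    summ[[i]] <- data.frame(sweeps = record_sweeps[i],
                            n_nuclei = nrow(big),
                            n_bonds = total,
                            largest = if (nrow(nuc)) max(nuc$size) else 0L,
                            mean_size = if (nrow(big)) mean(big$size) else NA_real_)
  }
  structure(list(times = record_sweeps, nuclei = nuclei,
                 summary = do.call(rbind, summ), system = sys),
            class = "mc_trajectory")
}

#' Replicate-averaged radial profiles and nucleus counts
#'
#' Runs `cfg$n_replicates` independent trajectories (replicate r seeded
#' with `cfg$seed + r - 1`), pools the nucleus records per recorded
#' time, and returns binned radial profiles plus the per-replicate
#' nucleus-count series.
#'
#' @inheritParams mc_trajectory
#' @param bin_width Radial bin width (lattice units), default 1.
#' @param margin Profile extends to droplet_radius + margin; default 5.
#' @return List of class `mc_ensemble`: `profiles` (list per time of
#'   the averaged [radial_profile()]), `counts` (matrix replicates x
#'   times of nucleus counts), `summary` (replicate-averaged
#'   data.frame), `times`, `cfg`.
#' @export
mc_replicates <- function(cfg, record_sweeps, relax_sweeps = 0,
                          min_size = 10, min_frac = 0.02, bin_width = 1,
                          margin = 5) {
  edges <- seq(0, cfg$droplet_radius + margin, by = bin_width)
  per_time <- vector("list", length(record_sweeps))
  counts <- matrix(0L, cfg$n_replicates, length(record_sweeps))
  summs <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    tr <- mc_trajectory(cfg, record_sweeps, seed = cfg$seed + r - 1L,
                        relax_sweeps = relax_sweeps, min_size = min_size,
                        min_frac = min_frac)
    for (i in seq_along(record_sweeps)) {
      nuc <- tr$nuclei[[i]]
      if (nrow(nuc)) nuc$replicate <- r
      per_time[[i]] <- c(per_time[[i]], list(nuc))
      counts[r, i] <- tr$summary$n_nuclei[i]
    }
    summs[[r]] <- tr$summary
  }
  profiles <- lapply(per_time, function(lst) {
    radial_profile(do.call(rbind, lst), edges)
  })
  avg <- summs[[1]]
  for (col in c("n_nuclei", "n_bonds", "largest")) {
    avg[[col]] <- rowMeans(vapply(summs, function(s) as.numeric(s[[col]]),
                                  numeric(nrow(avg))))
  }
  structure(list(profiles = profiles, counts = counts, summary = avg,
                 pooled = per_time, times = record_sweeps, cfg = cfg),
            class = "mc_ensemble")
}

#' Longest relaxation time of the crystallizable block
#'
#' Runs the system with the parallel (crystallization) attraction
#' switched off and measures the decay of the B-block end-to-end vector
#' fluctuation autocorrelation, averaged over chains:
#' `C(dt) = <du(t) . du(t+dt)> / <|du|^2>` with `du = u - <u>_chain`.
#' Subtracting the per-chain time mean is required because grafted
#' chains keep a persistent radial component of `u` that never
#' decorrelates; the fluctuation part relaxes like the free-solution
#' chain.  tau is the lag (in sweeps) at which C first falls below
#' 1/e, linearly interpolated.
#'
#' @param sys A `chain_system`.
#' @param max_sweeps Sampling budget (sweeps).
#' @param sample_every Sweeps between samples.
#' @return List: `tau_sweeps`, the autocorrelation data.frame
#'   (`lag_sweeps`, `acf`), and the relaxed system.  Errors if the
#'   autocorrelation does not decay below 1/e within the budget.
#' @export
relax_and_measure_tau <- function(sys, max_sweeps = 400, sample_every = 2) {
  stopifnot(inherits(sys, "chain_system"))
  cfg <- sys$cfg
  n_samp <- floor(max_sweeps / sample_every)
  if (n_samp < 4) stop("sampling budget too small")
  ee <- vector("list", n_samp + 1)
  ee[[1]] <- b_block_end_to_end(sys)
  for (i in seq_len(n_samp)) {
    sys <- mc_run(sys, sample_every, ep_over_ec = 0)
    ee[[i + 1]] <- b_block_end_to_end(sys)
    if (attr(sys, "accepted") == 0)
      stop("frozen system: no accepted moves while measuring tau")
  }
  nt <- length(ee)
  ubar <- Reduce(`+`, ee) / nt
  ee <- lapply(ee, function(u) u - ubar)
  norm0 <- mean(vapply(ee, function(u) mean(rowSums(u^2)), numeric(1)))
  if (norm0 <= 0) stop("frozen system: no end-to-end fluctuations")
  max_lag <- floor(nt / 2)
  acf <- vapply(0:max_lag, function(l) {
    v <- vapply(seq_len(nt - l), function(t0)
      mean(rowSums(ee[[t0]] * ee[[t0 + l]])), numeric(1))
    mean(v) / norm0
  }, numeric(1))
  lags <- (0:max_lag) * sample_every
  below <- which(acf < exp(-1))
  if (length(below) == 0)
    stop("autocorrelation did not decay to 1/e within ", max_sweeps,
         " sweeps; increase max_sweeps")
  i2 <- below[1]; i1 <- i2 - 1
  tau <- lags[i1] + (acf[i1] - exp(-1)) / (acf[i1] - acf[i2]) *
    (lags[i2] - lags[i1])
  list(tau_sweeps = tau,
       acf = data.frame(lag_sweeps = lags, acf = acf),
       system = sys)
}

#' B-block end-to-end vectors
#'
#' Minimal-image end-to-end vector of the crystallizable block of each
#' chain (sum of wrapped bond vectors).
#'
#' @param sys A `chain_system`.
#' @return Matrix n_chains x 3.
#' @keywords internal
b_block_end_to_end <- function(sys) {
  cfg <- sys$cfg
  N <- cfg$n_a + cfg$n_b
  pos <- sys$pos
  box <- cfg$box
  out <- matrix(0, cfg$n_chains, 3)
  for (k in 1:3) {
    x <- matrix(pos[, k], nrow = N)
    d <- diff(x)[(cfg$n_a + 1):(N - 1), , drop = FALSE]
    d <- d - box[k] * round(d / box[k])
    out[, k] <- colSums(d)
  }
  out
}
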