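# Independent brute-force oracles for the lattice-MC energy model and
# crystalline-bond definition, written against the model description
# only (no shared code with the compiled path).

nb_offsets <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

wrap_diff <- function(d, L) d - L * round(d / L)

# assemble a chain_system from hand-built 0-based positions
make_system <- function(pos, cfg) {
  stopifnot(nrow(pos) == cfg$n_chains * (cfg$n_a + cfg$n_b))
  structure(list(pos = pos, cfg = cfg), class = "chain_system")
}

# site key (1-based) for an occupancy lookup table
site_key <- function(p, box) p[, 1] + box[1] * (p[, 2] + box[2] * p[, 3]) + 1

oracle_energy_counts <- function(sys) {
  cfg <- sys$cfg
  box <- cfg$box
  N <- cfg$n_a + cfg$n_b
  pos <- sys$pos
  nmono <- nrow(pos)
  idx <- rep(seq_len(N), cfg$n_chains)
  isB <- idx > cfg$n_a

  # non-collinear consecutive bond pairs
  ncol_ct <- 0
  for (ch in seq_len(cfg$n_chains)) {
    rows <- ((ch - 1) * N + 1):(ch * N)
    for (j in rows[-c(1, length(rows))]) {
      v1 <- wrap_diff(pos[j, ] - pos[j - 1, ], box)
      v2 <- wrap_diff(pos[j + 1, ] - pos[j, ], box)
      if (any(v1 != v2)) ncol_ct <- ncol_ct + 1
    }
  }

  # parallel adjacent B-bond pairs (brute-force double loop)
  b_from <- which(idx < N)
  bvec <- t(vapply(b_from, function(m)
    wrap_diff(pos[m + 1, ] - pos[m, ], box), numeric(3)))
  bb <- which(isB[b_from] & isB[b_from + 1])
  par_ct <- 0
  if (length(bb) > 1) {
    for (i in 1:(length(bb) - 1)) for (j in (i + 1):length(bb)) {
      mi <- b_from[bb[i]]; mj <- b_from[bb[j]]
      if (length(intersect(c(mi, mi + 1), c(mj, mj + 1))) > 0) next
      vi <- bvec[bb[i], ]; vj <- bvec[bb[j], ]
      if (all(vi == vj)) q1 <- pos[mj, ]
      else if (all(vi == -vj)) q1 <- pos[mj + 1, ]
      else next
      delta <- wrap_diff(q1 - pos[mi, ], box)
      if (all(abs(delta) <= 1)) par_ct <- par_ct + 1
    }
  }

  # unlike contacts: B-water, A-oil, A-B over the 26-neighbourhood
  occ <- rep(NA_integer_, prod(box))
  occ[site_key(pos, box)] <- seq_len(nmono)
  all_sites <- as.matrix(expand.grid(x = 0:(box[1] - 1), y = 0:(box[2] - 1),
                                     z = 0:(box[3] - 1)))
  dd <- sweep(all_sites, 2, cfg$droplet_center)
  for (k in 1:3) dd[, k] <- wrap_diff(dd[, k], box[k])
  oil <- rowSums(dd^2) < cfg$droplet_radius^2
  oil_lookup <- rep(NA, prod(box))
  oil_lookup[site_key(all_sites, box)] <- oil
  unlike <- 0
  for (m in seq_len(nmono)) {
    for (t in seq_len(nrow(nb_offsets))) {
      q <- (pos[m, ] + nb_offsets[t, ]) %% box
      key <- q[1] + box[1] * (q[2] + box[2] * q[3]) + 1
      o <- occ[key]
      if (!is.na(o)) {
        if (isB[m] != isB[o]) unlike <- unlike + 0.5
      } else {
        q_oil <- oil_lookup[key]
        if (isB[m] && !q_oil) unlike <- unlike + 1
        if (!isB[m] && q_oil) unlike <- unlike + 1
      }
    }
  }
  list(noncollinear = ncol_ct, parallel_pairs = par_ct,
       unlike_contacts = unlike,
       energy = ncol_ct + cfg$b_over_ec * unlike -
         cfg$ep_over_ec * par_ct)
}

# per-B-bond parallel-partner counts by brute force
oracle_parallel_counts <- function(sys) {
  cfg <- sys$cfg
  box <- cfg$box
  N <- cfg$n_a + cfg$n_b
  pos <- sys$pos
  idx <- rep(seq_len(N), cfg$n_chains)
  isB <- idx > cfg$n_a
  b_from <- which(idx < N)
  bvec <- t(vapply(b_from, function(m)
    wrap_diff(pos[m + 1, ] - pos[m, ], box), numeric(3)))
  bb <- which(isB[b_from] & isB[b_from + 1])
  counts <- setNames(integer(length(bb)), b_from[bb] - 1)  # 0-based ids
  for (i in seq_along(bb)) {
    mi <- b_from[bb[i]]
    for (j in seq_along(bb)) {
      if (i == j) next
      mj <- b_from[bb[j]]
      if (length(intersect(c(mi, mi + 1), c(mj, mj + 1))) > 0) next
      vi <- bvec[bb[i], ]; vj <- bvec[bb[j], ]
      if (all(vi == vj)) q1 <- pos[mj, ]
      else if (all(vi == -vj)) q1 <- pos[mj + 1, ]
      else next
      delta <- wrap_diff(q1 - pos[mi, ], box)
      if (all(abs(delta) <= 1)) counts[i] <- counts[i] + 1
    }
  }
  counts
}

# check chain connectivity + single occupancy of a system
expect_valid_system <- function(sys) {
  cfg <- sys$cfg
  N <- cfg$n_a + cfg$n_b
  pos <- sys$pos
  expect_equal(nrow(pos), cfg$n_chains * N)
  expect_equal(anyDuplicated(site_key(pos, cfg$box)), 0)
  for (ch in seq_len(cfg$n_chains)) {
    rows <- ((ch - 1) * N + 1):(ch * N)
    d <- pos[rows[-1], , drop = FALSE] - pos[rows[-length(rows)], , drop = FALSE]
    for (k in 1:3) d[, k] <- wrap_diff(d[, k], cfg$box[k])
    expect_true(all(abs(d) <= 1))
    expect_true(all(rowSums(abs(d)) > 0))
  }
}
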