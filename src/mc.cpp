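// Coarse-grained lattice Monte-Carlo core for diblock-copolymer
// crystallization at a spherical liquid-liquid interface.
//
// Simple cubic lattice, coordination 26 (axial + face-diagonal +
// body-diagonal bonds), single occupancy, periodic boundaries.  Vacant
// sites are solvent, typed by a fixed spherical region map: oil inside
// the droplet, water outside.  Chains move by micro-relaxation: a
// monomer exchanges with a vacant neighbour site, with sliding
// diffusion along the chain when the single-site move would break
// connectivity.  Metropolis acceptance at reduced temperature
// kT/Ec.  Energies (in units of Ec): +1 per non-collinear consecutive
// bond pair, +B/Ec per unlike contact (B-water, A-oil, A-B), -Ep/Ec
// per parallel adjacent pair of crystallizable (B-B) bonds.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

static int NB[26][3];
static bool nb_ready = false;
static void init_nb() {
  if (nb_ready) return;
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        NB[k][0] = dx; NB[k][1] = dy; NB[k][2] = dz; ++k;
      }
  nb_ready = true;
}

struct Lat {
  int X, Y, Z, nA, nB, N, nchain, nmono;
  double cx, cy, cz, R2;
  std::vector<int> occ;                 // site -> monomer id or -1
  std::vector<int> px, py, pz;          // monomer -> coords
  std::vector<long long> stamp;         // site -> move id (affected-set mark)
  long long cur_stamp = 0;
  std::vector<char> reg;                // site -> 1 oil (inside), 0 water

  void init(const IntegerMatrix& pos, IntegerVector box,
            NumericVector center, double radius,
            int n_a, int n_b, int n_chains) {
    init_nb();
    X = box[0]; Y = box[1]; Z = box[2];
    cx = center[0]; cy = center[1]; cz = center[2];
    R2 = radius * radius;
    nA = n_a; nB = n_b; N = n_a + n_b; nchain = n_chains;
    nmono = pos.nrow();
    px.resize(nmono); py.resize(nmono); pz.resize(nmono);
    occ.assign((size_t)X * Y * Z, -1);
    stamp.assign((size_t)X * Y * Z, -1);
    reg.assign((size_t)X * Y * Z, 0);
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y)
        for (int x = 0; x < X; ++x)
          if (inside_slow(x, y, z)) reg[site(x, y, z)] = 1;
    for (int m = 0; m < nmono; ++m) {
      px[m] = pos(m, 0); py[m] = pos(m, 1); pz[m] = pos(m, 2);
      occ[site(px[m], py[m], pz[m])] = m;
    }
  }
  // wrap for values at most one box length out of range (all hot paths)
  inline int wx(int x) const { return x < 0 ? x + X : (x >= X ? x - X : x); }
  inline int wy(int y) const { return y < 0 ? y + Y : (y >= Y ? y - Y : y); }
  inline int wz(int z) const { return z < 0 ? z + Z : (z >= Z ? z - Z : z); }
  inline size_t site(int x, int y, int z) const {
    return ((size_t)z * Y + y) * X + x;
  }
  inline int d1(int a, int b, int L) const {  // minimal-image component
    int d = a - b;
    if (d > L / 2) d -= L;
    if (d < -L / 2) d += L;
    return d;
  }
  inline bool adjacent(int x1, int y1, int z1, int x2, int y2, int z2) const {
    int dx = d1(x1, x2, X), dy = d1(y1, y2, Y), dz = d1(z1, z2, Z);
    if (dx == 0 && dy == 0 && dz == 0) return false;
    return std::abs(dx) <= 1 && std::abs(dy) <= 1 && std::abs(dz) <= 1;
  }
  inline bool inside_slow(int x, int y, int z) const {
    double dx = x - cx, dy = y - cy, dz = z - cz;
    dx -= X * std::round(dx / X);
    dy -= Y * std::round(dy / Y);
    dz -= Z * std::round(dz / Z);
    return dx * dx + dy * dy + dz * dz < R2;
  }
  inline bool inside(int x, int y, int z) const {
    return reg[site(x, y, z)] != 0;
  }
  inline bool isB(int m) const { return (m % N) >= nA; }
  // bond vector monomer k -> k+1, minimal image (components in -1..1)
  inline void bvec(int k, int& dx, int& dy, int& dz) const {
    dx = d1(px[k + 1], px[k], X);
    dy = d1(py[k + 1], py[k], Y);
    dz = d1(pz[k + 1], pz[k], Z);
  }
  inline bool validBond(int k) const {            // chain bond k..k+1
    return (k % N) < N - 1;
  }
  inline bool bBond(int k) const { return validBond(k) && isB(k) && isB(k + 1); }

  // count parallel neighbouring B-bonds of B-bond k; weight 0.5 for
  // partners inside the affected range [blo,bhi] of chain c (pass
  // blo > bhi to disable weighting -> plain count)
  double parallelPartners(int k, int blo, int bhi) const {
    int vx, vy, vz; bvec(k, vx, vy, vz);
    double w = 0.0;
    for (int t = 0; t < 26; ++t) {
      int q1x = wx(px[k] + NB[t][0]), q1y = wy(py[k] + NB[t][1]),
          q1z = wz(pz[k] + NB[t][2]);
      int q2x = wx(q1x + vx), q2y = wy(q1y + vy), q2z = wz(q1z + vz);
      int a = occ[site(q1x, q1y, q1z)];
      if (a < 0) continue;
      int b = occ[site(q2x, q2y, q2z)];
      if (b < 0) continue;
      if (a / N != b / N) continue;               // same chain
      int lo = a < b ? a : b;
      if (std::abs(a - b) != 1) continue;         // consecutive monomers
      if (!bBond(lo)) continue;                   // B-B bond
      if (a == k || a == k + 1 || b == k || b == k + 1) continue;
      w += (lo >= blo && lo <= bhi) ? 0.5 : 1.0;
    }
    return w;
  }

  // unlike-contact weight of the pair (state at s1, state at s2)
  inline double contactU(int m1, bool in1, int m2, bool in2) const {
    // m >= 0 monomer, else solvent typed by region (in = oil)
    if (m1 >= 0 && m2 >= 0) return isB(m1) != isB(m2) ? 1.0 : 0.0;
    if (m1 < 0 && m2 < 0) return 0.0;
    int m = m1 >= 0 ? m1 : m2;
    bool oil = m1 >= 0 ? in2 : in1;
    if (isB(m)) return oil ? 0.0 : 1.0;           // B-water unlike
    return oil ? 1.0 : 0.0;                       // A-oil unlike
  }
};

// full-system energy term counts
// [[Rcpp::export]]
NumericVector mc_energy_counts_cpp(IntegerMatrix pos, IntegerVector box,
                                   NumericVector center, double radius,
                                   int n_a, int n_b, int n_chains) {
  Lat L; L.init(pos, box, center, radius, n_a, n_b, n_chains);
  double ncol = 0, par = 0, unlike = 0;
  for (int c = 0; c < L.nchain; ++c) {
    for (int j = c * L.N + 1; j < (c + 1) * L.N - 1; ++j) {
      int ax, ay, az, bx, by, bz;
      L.bvec(j - 1, ax, ay, az); L.bvec(j, bx, by, bz);
      if (ax != bx || ay != by || az != bz) ncol += 1;
    }
    for (int k = c * L.N; k < (c + 1) * L.N - 1; ++k)
      if (L.bBond(k)) par += L.parallelPartners(k, 1, 0);
  }
  par /= 2.0;                                     // each pair seen twice
  for (int m = 0; m < L.nmono; ++m) {
    bool inm = L.inside(L.px[m], L.py[m], L.pz[m]);
    for (int t = 0; t < 26; ++t) {
      int qx = L.wx(L.px[m] + NB[t][0]), qy = L.wy(L.py[m] + NB[t][1]),
          qz = L.wz(L.pz[m] + NB[t][2]);
      int o = L.occ[L.site(qx, qy, qz)];
      double u = L.contactU(m, inm, o, L.inside(qx, qy, qz));
      unlike += (o >= 0) ? 0.5 * u : u;           // mm pairs seen twice
    }
  }
  return NumericVector::create(_["noncollinear"] = ncol,
                               _["parallel_pairs"] = par,
                               _["unlike_contacts"] = unlike);
}

// local energy of the affected term set for monomers [lo..hi] of one
// chain, given the affected SITE set (old+new positions), pre-marked
// in L.stamp with L.cur_stamp.
static double local_energy(Lat& L, int lo, int hi,
                           const std::vector<int>& sx,
                           const std::vector<int>& sy,
                           const std::vector<int>& sz,
                           double ep, double bmix) {
  int c = lo / L.N;
  int c0 = c * L.N, c1 = c0 + L.N - 1;
  double e = 0;
  // chain-rigidity terms with middle monomer in [lo-1, hi+1]
  int jlo = std::max(c0 + 1, lo - 1), jhi = std::min(c1 - 1, hi + 1);
  for (int j = jlo; j <= jhi; ++j) {
    int ax, ay, az, bx, by, bz;
    L.bvec(j - 1, ax, ay, az); L.bvec(j, bx, by, bz);
    if (ax != bx || ay != by || az != bz) e += 1.0;
  }
  // parallel-packing terms involving an affected bond
  int blo = std::max(c0, lo - 1), bhi = std::min(c1 - 1, hi);
  for (int k = blo; k <= bhi; ++k)
    if (L.bBond(k)) e -= ep * L.parallelPartners(k, blo, bhi);
  // contact terms over affected sites (pairs inside the set halved)
  size_t ns = sx.size();
  for (size_t i = 0; i < ns; ++i) {
    int m1 = L.occ[L.site(sx[i], sy[i], sz[i])];
    bool in1 = L.inside(sx[i], sy[i], sz[i]);
    for (int t = 0; t < 26; ++t) {
      int qx = L.wx(sx[i] + NB[t][0]), qy = L.wy(sy[i] + NB[t][1]),
          qz = L.wz(sz[i] + NB[t][2]);
      size_t qs = L.site(qx, qy, qz);
      bool in_set = L.stamp[qs] == L.cur_stamp;
      int m2 = L.occ[qs];
      double u = L.contactU(m1, in1, m2, L.inside(qx, qy, qz));
      e += bmix * (in_set ? 0.5 * u : u);
    }
  }
  return e;
}

// [[Rcpp::export]]
List mc_run_cpp(IntegerMatrix pos, IntegerVector box, NumericVector center,
                double radius, int n_a, int n_b, int n_chains,
                double sweeps, double tstar, double ep, double bmix) {
  IntegerMatrix out = clone(pos);
  Lat L; L.init(out, box, center, radius, n_a, n_b, n_chains);
  double delta_e = 0;
  long long attempted = 0, accepted = 0;
  long long nmoves = (long long)(sweeps * L.nmono + 0.5);
  std::vector<int> nlo_x, nlo_y, nlo_z;           // proposed new coords
  std::vector<int> old_x, old_y, old_z;
  std::vector<int> ax, ay, az;                    // affected site set

  for (long long it = 0; it < nmoves; ++it) {
    ++attempted;
    int m = (int)(unif_rand() * L.nmono); if (m >= L.nmono) m = L.nmono - 1;
    int t = (int)(unif_rand() * 26); if (t >= 26) t = 25;
    int sx_ = L.wx(L.px[m] + NB[t][0]), sy_ = L.wy(L.py[m] + NB[t][1]),
        sz_ = L.wz(L.pz[m] + NB[t][2]);
    if (L.occ[L.site(sx_, sy_, sz_)] >= 0) continue;   // occupied target
    int c = m / L.N, c0 = c * L.N, c1 = c0 + L.N - 1;

    // build the moved segment [lo..hi] and its proposed positions;
    // direction +1 slides toward the chain tail, -1 toward the head
    int lo = m, hi = m, dir = 0;
    bool ok = true;
    if (m == c0 && m == c1) {
      // single-monomer chain (not used, but safe)
    } else if (m == c0) {
      dir = +1;
    } else if (m == c1) {
      dir = -1;
    } else {
      bool aPrev = L.adjacent(sx_, sy_, sz_, L.px[m - 1], L.py[m - 1], L.pz[m - 1]);
      bool aNext = L.adjacent(sx_, sy_, sz_, L.px[m + 1], L.py[m + 1], L.pz[m + 1]);
      if (aPrev && aNext) dir = 0;
      else if (aPrev) dir = +1;
      else if (aNext) dir = -1;
      else ok = false;
    }
    if (!ok) continue;

    nlo_x.clear(); nlo_y.clear(); nlo_z.clear();
    nlo_x.push_back(sx_); nlo_y.push_back(sy_); nlo_z.push_back(sz_);
    if (dir == +1) {
      int j = m;
      while (j + 1 <= c1) {
        int nx = nlo_x.back(), ny = nlo_y.back(), nz = nlo_z.back();
        if (L.adjacent(nx, ny, nz, L.px[j + 1], L.py[j + 1], L.pz[j + 1])) break;
        nlo_x.push_back(L.px[j]); nlo_y.push_back(L.py[j]); nlo_z.push_back(L.pz[j]);
        ++j;
      }
      hi = j;
    } else if (dir == -1) {
      int j = m;
      while (j - 1 >= c0) {
        int nx = nlo_x.back(), ny = nlo_y.back(), nz = nlo_z.back();
        if (L.adjacent(nx, ny, nz, L.px[j - 1], L.py[j - 1], L.pz[j - 1])) break;
        nlo_x.push_back(L.px[j]); nlo_y.push_back(L.py[j]); nlo_z.push_back(L.pz[j]);
        --j;
      }
      lo = j;
    }
    int seg = hi - lo + 1;
    // proposal list runs from the picked monomer outward; map to [lo..hi]
    old_x.resize(seg); old_y.resize(seg); old_z.resize(seg);
    ax.clear(); ay.clear(); az.clear();
    for (int i = 0; i < seg; ++i) {
      int j = lo + i;
      old_x[i] = L.px[j]; old_y[i] = L.py[j]; old_z[i] = L.pz[j];
      ax.push_back(old_x[i]); ay.push_back(old_y[i]); az.push_back(old_z[i]);
    }
    // new sites: only the target s is not an old site
    ax.push_back(sx_); ay.push_back(sy_); az.push_back(sz_);
    L.cur_stamp = it;
    for (size_t i = 0; i < ax.size(); ++i)
      L.stamp[L.site(ax[i], ay[i], az[i])] = it;

    double e_before = local_energy(L, lo, hi, ax, ay, az, ep, bmix);

    // apply: vacate old, place new
    for (int i = 0; i < seg; ++i)
      L.occ[L.site(old_x[i], old_y[i], old_z[i])] = -1;
    if (dir >= 0) {   // proposal ordered m, m+1, ..., hi  (lo == m)
      for (int i = 0; i < seg; ++i) {
        int j = lo + i;
        L.px[j] = nlo_x[i]; L.py[j] = nlo_y[i]; L.pz[j] = nlo_z[i];
      }
    } else {          // proposal ordered m, m-1, ..., lo  (hi == m)
      for (int i = 0; i < seg; ++i) {
        int j = hi - i;
        L.px[j] = nlo_x[i]; L.py[j] = nlo_y[i]; L.pz[j] = nlo_z[i];
      }
    }
    for (int j = lo; j <= hi; ++j)
      L.occ[L.site(L.px[j], L.py[j], L.pz[j])] = j;

    double e_after = local_energy(L, lo, hi, ax, ay, az, ep, bmix);
    double dE = e_after - e_before;
    bool accept = dE <= 0 || unif_rand() < std::exp(-dE / tstar);
    if (accept) {
      delta_e += dE;
      ++accepted;
    } else {
      for (int j = lo; j <= hi; ++j)
        L.occ[L.site(L.px[j], L.py[j], L.pz[j])] = -1;
      for (int i = 0; i < seg; ++i) {
        int j = lo + i;
        L.px[j] = old_x[i]; L.py[j] = old_y[i]; L.pz[j] = old_z[i];
        L.occ[L.site(old_x[i], old_y[i], old_z[i])] = j;
      }
    }
  }
  for (int m = 0; m < L.nmono; ++m) {
    out(m, 0) = L.px[m]; out(m, 1) = L.py[m]; out(m, 2) = L.pz[m];
  }
  return List::create(_["pos"] = out, _["delta_e"] = delta_e,
                      _["attempted"] = (double)attempted,
                      _["accepted"] = (double)accepted);
}

// [[Rcpp::export]]
IntegerMatrix mc_build_cpp(IntegerVector box, NumericVector center,
                           double radius, int n_chains, int n_a, int n_b,
                           int chain_tries) {
  init_nb();
  int N = n_a + n_b, nmono = n_chains * N;
  IntegerMatrix pos(nmono, 3);
  Lat L;
  {
    IntegerMatrix empty(0, 3);
    L.init(empty, box, center, radius, n_a, n_b, 0);
  }
  L.nmono = nmono; L.nchain = n_chains; L.N = N; L.nA = n_a; L.nB = n_b;
  L.px.assign(nmono, 0); L.py.assign(nmono, 0); L.pz.assign(nmono, 0);

  std::vector<int> cand(26);
  for (int c = 0; c < n_chains; ++c) {
    bool placed_chain = false;
    for (int tri = 0; tri < chain_tries && !placed_chain; ++tri) {
      std::vector<int> done_x, done_y, done_z;    // sites placed this try
      // junction B monomer just inside the interface
      int jx = 0, jy = 0, jz = 0;
      bool found = false;
      for (int k = 0; k < 200 && !found; ++k) {
        double gx = norm_rand(), gy = norm_rand(), gz = norm_rand();
        double nrm = std::sqrt(gx * gx + gy * gy + gz * gz);
        if (nrm < 1e-12) continue;
        double r = radius - 0.1 - 1.3 * unif_rand();
        jx = L.wx((int)std::lround(L.cx + gx / nrm * r));
        jy = L.wy((int)std::lround(L.cy + gy / nrm * r));
        jz = L.wz((int)std::lround(L.cz + gz / nrm * r));
        if (L.occ[L.site(jx, jy, jz)] < 0 && L.inside(jx, jy, jz)) found = true;
      }
      if (!found) continue;
      int base = c * N;
      bool fail = false;
      auto place = [&](int m, int x, int y, int z) {
        L.px[m] = x; L.py[m] = y; L.pz[m] = z;
        L.occ[L.site(x, y, z)] = m;
        done_x.push_back(x); done_y.push_back(y); done_z.push_back(z);
      };
      place(base + n_a, jx, jy, jz);
      // B block inward random walk (stays inside droplet)
      for (int idx = n_a + 1; idx < N && !fail; ++idx) {
        int prev = base + idx - 1, nc = 0;
        for (int t = 0; t < 26; ++t) {
          int x = L.wx(L.px[prev] + NB[t][0]), y = L.wy(L.py[prev] + NB[t][1]),
              z = L.wz(L.pz[prev] + NB[t][2]);
          if (L.occ[L.site(x, y, z)] < 0 && L.inside(x, y, z)) cand[nc++] = t;
        }
        if (nc == 0) { fail = true; break; }
        int t = cand[(int)(unif_rand() * nc)];
        place(base + idx, L.wx(L.px[prev] + NB[t][0]),
              L.wy(L.py[prev] + NB[t][1]), L.wz(L.pz[prev] + NB[t][2]));
      }
      // A block outward random walk (stays outside)
      for (int idx = n_a - 1; idx >= 0 && !fail; --idx) {
        int next = base + idx + 1, nc = 0;
        for (int t = 0; t < 26; ++t) {
          int x = L.wx(L.px[next] + NB[t][0]), y = L.wy(L.py[next] + NB[t][1]),
              z = L.wz(L.pz[next] + NB[t][2]);
          if (L.occ[L.site(x, y, z)] < 0 && !L.inside(x, y, z)) cand[nc++] = t;
        }
        if (nc == 0) { fail = true; break; }
        int t = cand[(int)(unif_rand() * nc)];
        place(base + idx, L.wx(L.px[next] + NB[t][0]),
              L.wy(L.py[next] + NB[t][1]), L.wz(L.pz[next] + NB[t][2]));
      }
      if (fail) {
        for (size_t i = 0; i < done_x.size(); ++i)
          L.occ[L.site(done_x[i], done_y[i], done_z[i])] = -1;
      } else placed_chain = true;
    }
    if (!placed_chain)
      stop("infeasible packing: placed only %d of %d chains at this "
           "interface", c, n_chains);
  }
  for (int m = 0; m < nmono; ++m) {
    pos(m, 0) = L.px[m]; pos(m, 1) = L.py[m]; pos(m, 2) = L.pz[m];
  }
  return pos;
}

// crystalline-bond detection + connected-component clustering
// [[Rcpp::export]]
DataFrame mc_crystal_bonds_cpp(IntegerMatrix pos, IntegerVector box,
                               NumericVector center, double radius,
                               int n_a, int n_b, int n_chains,
                               int min_parallel) {
  Lat L; L.init(pos, box, center, radius, n_a, n_b, n_chains);
  std::vector<int> bond_m;                        // first monomer of bond
  for (int c = 0; c < L.nchain; ++c)
    for (int k = c * L.N; k < (c + 1) * L.N - 1; ++k)
      if (L.bBond(k) &&
          L.parallelPartners(k, 1, 0) >= (double)min_parallel)
        bond_m.push_back(k);
  int nb = (int)bond_m.size();

  // union-find over bonds; adjacency: any endpoint within the
  // 26-neighbourhood (or same site) of the other bond's endpoints
  std::vector<int> parent(nb);
  for (int i = 0; i < nb; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  auto unite = [&](int i, int j) {
    i = find(i); j = find(j); if (i != j) parent[i] = j;
  };
  std::vector<int> head((size_t)L.X * L.Y * L.Z, -1), nxt(2 * nb, -1);
  auto reg = [&](int ep_idx, size_t s) { nxt[ep_idx] = head[s]; head[s] = ep_idx; };
  for (int i = 0; i < nb; ++i) {
    int k = bond_m[i];
    reg(2 * i, L.site(L.px[k], L.py[k], L.pz[k]));
    reg(2 * i + 1, L.site(L.px[k + 1], L.py[k + 1], L.pz[k + 1]));
  }
  for (int i = 0; i < nb; ++i) {
    for (int e = 0; e < 2; ++e) {
      int k = bond_m[i] + e;
      for (int t = -1; t < 26; ++t) {
        int x = L.px[k], y = L.py[k], z = L.pz[k];
        if (t >= 0) { x = L.wx(x + NB[t][0]); y = L.wy(y + NB[t][1]); z = L.wz(z + NB[t][2]); }
        for (int j = head[L.site(x, y, z)]; j >= 0; j = nxt[j])
          unite(i, j / 2);
      }
    }
  }
  std::vector<int> cluster(nb), relabel;
  for (int i = 0; i < nb; ++i) {
    int r = find(i);
    int id = -1;
    for (size_t q = 0; q < relabel.size(); ++q)
      if (relabel[q] == r) { id = (int)q; break; }
    if (id < 0) { relabel.push_back(r); id = (int)relabel.size() - 1; }
    cluster[i] = id;
  }
  IntegerVector mm(nb), x1(nb), y1(nb), z1(nb), dx(nb), dy(nb), dz(nb), cl(nb);
  NumericVector np(nb);
  for (int i = 0; i < nb; ++i) {
    int k = bond_m[i];
    mm[i] = k; x1[i] = L.px[k]; y1[i] = L.py[k]; z1[i] = L.pz[k];
    int a, b, cvec; L.bvec(k, a, b, cvec);
    dx[i] = a; dy[i] = b; dz[i] = cvec;
    np[i] = L.parallelPartners(k, 1, 0);
    cl[i] = cluster[i] + 1;
  }
  return DataFrame::create(_["monomer"] = mm, _["x"] = x1, _["y"] = y1,
                           _["z"] = z1, _["dx"] = dx, _["dy"] = dy,
                           _["dz"] = dz, _["n_parallel"] = np,
                           _["cluster"] = cl);
}
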