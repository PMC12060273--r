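// Nonbonded kernels: Debye-Hueckel electrostatics + Lennard-Jones excluded
// volume over flattened element arrays, with cell-list neighbor search.
// Element metadata (kind, core_id, chain_id, chain_pos, excl_core) encodes
// the exclusion rules: intra-rigid-body pairs, bonded chain neighbors, and
// tail/LH beads against their own attachment core.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// kind codes: 0 core charge, 1 DNA bead, 2 tail bead, 3 LH globular, 4 LH CTD

static inline bool excluded(int ki, int ci, int chi, int cpi, int exi,
                            int kj, int cj, int chj, int cpj, int exj) {
  // same rigid body: core charges of one core, LH globular beads with core
  if (ci != 0 && ci == cj) {
    bool rigid_i = (ki == 0 || ki == 3);
    bool rigid_j = (kj == 0 || kj == 3);
    if (rigid_i && rigid_j) return true;
  }
  // bonded neighbors within one chain (DNA linker, tail, LH)
  if (chi != 0 && chi == chj) {
    int d = cpi - cpj;
    if (d < 0) d = -d;
    if (d <= 1) return true;
  }
  // element vs the core it is attached/adjacent to
  if (kj == 0 && cj != 0 && cj == exi) return true;
  if (ki == 0 && ci != 0 && ci == exj) return true;
  return false;
}

// Flat counting-sort cell grid over the bounding box of the indexed points.
// The cell size is grown if needed to cap the total number of cells.
struct CellIndex {
  double cell, x0, y0, z0;
  int nx, ny, nz;
  std::vector<int> start;    // ncells + 1 offsets
  std::vector<int> order;    // point ids sorted by cell
  void build(const NumericMatrix& P, const std::vector<int>& ids, double c) {
    cell = c;
    if (ids.empty()) {
      nx = ny = nz = 0;
      start.assign(1, 0);
      order.clear();
      return;
    }
    double x1, y1, z1;
    x0 = x1 = P(ids[0], 0); y0 = y1 = P(ids[0], 1); z0 = z1 = P(ids[0], 2);
    for (int id : ids) {
      x0 = std::min(x0, P(id, 0)); x1 = std::max(x1, P(id, 0));
      y0 = std::min(y0, P(id, 1)); y1 = std::max(y1, P(id, 1));
      z0 = std::min(z0, P(id, 2)); z1 = std::max(z1, P(id, 2));
    }
    for (;;) {
      nx = (int)((x1 - x0) / cell) + 1;
      ny = (int)((y1 - y0) / cell) + 1;
      nz = (int)((z1 - z0) / cell) + 1;
      if ((double)nx * ny * nz <= 4e6) break;
      cell *= 2.0;
    }
    int ncells = nx * ny * nz;
    start.assign(ncells + 1, 0);
    std::vector<int> cid(ids.size());
    for (size_t k = 0; k < ids.size(); ++k) {
      int id = ids[k];
      cid[k] = cell_of(P(id, 0), P(id, 1), P(id, 2));
      start[cid[k] + 1]++;
    }
    for (int c2 = 0; c2 < ncells; ++c2) start[c2 + 1] += start[c2];
    order.assign(ids.size(), 0);
    std::vector<int> cur(start.begin(), start.end() - 1);
    for (size_t k = 0; k < ids.size(); ++k) order[cur[cid[k]]++] = ids[k];
  }
  inline int clampi(int v, int n) const {
    return v < 0 ? 0 : (v >= n ? n - 1 : v);
  }
  inline int cell_of(double x, double y, double z) const {
    int ix = clampi((int)((x - x0) / cell), nx);
    int iy = clampi((int)((y - y0) / cell), ny);
    int iz = clampi((int)((z - z0) / cell), nz);
    return (ix * ny + iy) * nz + iz;
  }
  template <class F>
  void neighbors(double x, double y, double z, F&& fun) const {
    if (order.empty()) return;
    int ix = (int)std::floor((x - x0) / cell);
    int iy = (int)std::floor((y - y0) / cell);
    int iz = (int)std::floor((z - z0) / cell);
    int xlo = std::max(ix - 1, 0), xhi = std::min(ix + 1, nx - 1);
    int ylo = std::max(iy - 1, 0), yhi = std::min(iy + 1, ny - 1);
    int zlo = std::max(iz - 1, 0), zhi = std::min(iz + 1, nz - 1);
    if (xlo > xhi || ylo > yhi || zlo > zhi) return;
    for (int cx = xlo; cx <= xhi; ++cx)
      for (int cy = ylo; cy <= yhi; ++cy) {
        int base = (cx * ny + cy) * nz;
        for (int cz = zlo; cz <= zhi; ++cz) {
          int c2 = base + cz;
          for (int k = start[c2]; k < start[c2 + 1]; ++k) fun(order[k]);
        }
      }
  }
};

struct PairAccum {
  double elec = 0.0, ev = 0.0;
  int overlaps = 0;
};

static inline void pair_energy(double dx, double dy, double dz,
                               double qq, double sig, double ke,
                               double kappa, double kev, double rcut2,
                               PairAccum& acc) {
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= rcut2) return;
  if (r2 < 1e-18) { acc.overlaps += 1; return; }
  double r = std::sqrt(r2);
  if (ke != 0.0 && qq != 0.0)
    acc.elec += ke * qq * std::exp(-kappa * r) / r;
  if (kev != 0.0) {
    double sr2 = sig * sig / r2;
    double sr6 = sr2 * sr2 * sr2;
    acc.ev += kev * (sr6 * sr6 - sr6);
  }
}

// [[Rcpp::export]]
List nb_total_cpp(NumericMatrix P, NumericVector q, IntegerVector kind,
                  IntegerVector core_id, IntegerVector chain_id,
                  IntegerVector chain_pos, IntegerVector excl_core,
                  IntegerVector active, NumericVector sigma,
                  double ke, double kappa, double kev, double rcut) {
  int n = P.nrow();
  std::vector<int> ids;
  ids.reserve(n);
  for (int i = 0; i < n; ++i)
    if (active[i]) ids.push_back(i);
  CellIndex ci;
  ci.build(P, ids, rcut);
  double rcut2 = rcut * rcut;
  PairAccum acc;
  for (int i : ids) {
    PairAccum local;
    ci.neighbors(P(i, 0), P(i, 1), P(i, 2), [&](int j) {
      if (j <= i) return;
      if (excluded(kind[i], core_id[i], chain_id[i], chain_pos[i], excl_core[i],
                   kind[j], core_id[j], chain_id[j], chain_pos[j], excl_core[j]))
        return;
      pair_energy(P(i, 0) - P(j, 0), P(i, 1) - P(j, 1), P(i, 2) - P(j, 2),
                  q[i] * q[j], 0.5 * (sigma[i] + sigma[j]), ke, kappa, kev,
                  rcut2, local);
    });
    acc.elec += local.elec;
    acc.ev += local.ev;
    acc.overlaps += local.overlaps;
  }
  return List::create(_["elec"] = acc.elec, _["ev"] = acc.ev,
                      _["overlaps"] = acc.overlaps);
}

// Energy change when the elements `moved` (1-based) take new coordinates
// `Pnew` (one row per moved element) and possibly new activity flags
// `active_new`. Returns old/new interaction energies of the moved set with
// the static set, plus (if internal = true) within the moved set.
// [[Rcpp::export]]
List nb_delta_cpp(NumericMatrix P, NumericVector q, IntegerVector kind,
                  IntegerVector core_id, IntegerVector chain_id,
                  IntegerVector chain_pos, IntegerVector excl_core,
                  IntegerVector active, NumericVector sigma,
                  IntegerVector moved, NumericMatrix Pnew,
                  IntegerVector active_new, bool internal,
                  double ke, double kappa, double kev, double rcut) {
  int n = P.nrow();
  int nm = moved.size();
  std::vector<char> is_moved(n, 0);
  for (int k = 0; k < nm; ++k) is_moved[moved[k] - 1] = 1;
  std::vector<int> stat;
  stat.reserve(n);
  for (int i = 0; i < n; ++i)
    if (!is_moved[i] && active[i]) stat.push_back(i);
  CellIndex ci;
  ci.build(P, stat, rcut);
  double rcut2 = rcut * rcut;
  PairAccum oldE, newE;
  for (int k = 0; k < nm; ++k) {
    int i = moved[k] - 1;
    if (active[i]) {
      ci.neighbors(P(i, 0), P(i, 1), P(i, 2), [&](int j) {
        if (excluded(kind[i], core_id[i], chain_id[i], chain_pos[i],
                     excl_core[i], kind[j], core_id[j], chain_id[j],
                     chain_pos[j], excl_core[j]))
          return;
        pair_energy(P(i, 0) - P(j, 0), P(i, 1) - P(j, 1), P(i, 2) - P(j, 2),
                    q[i] * q[j], 0.5 * (sigma[i] + sigma[j]), ke, kappa, kev,
                    rcut2, oldE);
      });
    }
    if (active_new[k]) {
      ci.neighbors(Pnew(k, 0), Pnew(k, 1), Pnew(k, 2), [&](int j) {
        if (excluded(kind[i], core_id[i], chain_id[i], chain_pos[i],
                     excl_core[i], kind[j], core_id[j], chain_id[j],
                     chain_pos[j], excl_core[j]))
          return;
        pair_energy(Pnew(k, 0) - P(j, 0), Pnew(k, 1) - P(j, 1),
                    Pnew(k, 2) - P(j, 2), q[i] * q[j],
                    0.5 * (sigma[i] + sigma[j]), ke, kappa, kev, rcut2, newE);
      });
    }
  }
  if (internal) {
    for (int a = 0; a < nm; ++a) {
      int i = moved[a] - 1;
      for (int b = a + 1; b < nm; ++b) {
        int j = moved[b] - 1;
        if (excluded(kind[i], core_id[i], chain_id[i], chain_pos[i],
                     excl_core[i], kind[j], core_id[j], chain_id[j],
                     chain_pos[j], excl_core[j]))
          continue;
        double qq = q[i] * q[j], sg = 0.5 * (sigma[i] + sigma[j]);
        if (active[i] && active[j])
          pair_energy(P(i, 0) - P(j, 0), P(i, 1) - P(j, 1), P(i, 2) - P(j, 2),
                      qq, sg, ke, kappa, kev, rcut2, oldE);
        if (active_new[a] && active_new[b])
          pair_energy(Pnew(a, 0) - Pnew(b, 0), Pnew(a, 1) - Pnew(b, 1),
                      Pnew(a, 2) - Pnew(b, 2), qq, sg, ke, kappa, kev,
                      rcut2, newE);
      }
    }
  }
  return List::create(_["elec_old"] = oldE.elec, _["ev_old"] = oldE.ev,
                      _["elec_new"] = newE.elec, _["ev_new"] = newE.ev,
                      _["overlaps"] = newE.overlaps);
}

static inline void rand_unit_vec(double* u) {
  for (;;) {
    double x = norm_rand(), y = norm_rand(), z = norm_rand();
    double n2 = x * x + y * y + z * z;
    if (n2 > 1e-12) {
      double n = std::sqrt(n2);
      u[0] = x / n; u[1] = y / n; u[2] = z / n;
      return;
    }
  }
}

// bond length from p(l) ~ l^2 exp(-h (l - l0)^2 / (2 kBT))
static inline double sample_bond(double l0, double h, double kBT) {
  double sd = std::sqrt(kBT / h);
  double lmax = l0 + 4 * sd;
  for (;;) {
    double l = l0 + sd * norm_rand();
    if (l > 0 && unif_rand() < (l / lmax) * (l / lmax)) return l;
  }
}

// Full configurational-bias regrowth of one histone tail: grows a new
// conformation and retraces the old one with `ntr` trials per bead,
// returning the log Rosenbluth weight ratio and the proposed coordinates.
// `cand` are candidate interaction partners (1-based, active, not this
// tail); trial-bead metadata mirrors nb_bead_cpp. Uses R's RNG.
// [[Rcpp::export]]
List cbmc_regrow_cpp(NumericMatrix P, NumericVector q, IntegerVector kind,
                     IntegerVector core_id, IntegerVector chain_id,
                     IntegerVector chain_pos, IntegerVector excl_core,
                     NumericVector sigma, IntegerVector cand,
                     NumericMatrix old_pos, NumericVector charges,
                     NumericVector attach, double sigma0, int core0,
                     int ntr, double l0t, double h_eff, double g_eff,
                     double kBT, double ke, double kappa, double kev,
                     double rcut) {
  int nb = old_pos.nrow();
  double rcut2 = rcut * rcut;
  double beta = 1.0 / kBT;
  NumericMatrix grown(nb, 3);
  std::vector<double> trials(ntr * 3), us(ntr), wts(ntr);

  auto bead_u = [&](const double* pos, const NumericMatrix& placed, int j) {
    // j is 0-based bead index; placed holds beads 0..j-1
    PairAccum acc;
    for (int k = 0; k < cand.size(); ++k) {
      int el = cand[k] - 1;
      if (excluded(2, core0, 0, 0, core0, kind[el], core_id[el],
                   chain_id[el], chain_pos[el], excl_core[el]))
        continue;
      pair_energy(pos[0] - P(el, 0), pos[1] - P(el, 1), pos[2] - P(el, 2),
                  charges[j] * q[el], 0.5 * (sigma0 + sigma[el]), ke, kappa,
                  kev, rcut2, acc);
    }
    if (acc.overlaps > 0) return R_PosInf;
    double u = acc.elec + acc.ev;
    for (int m = 0; m <= j - 2; ++m) {   // same-tail non-neighbors
      double dx = pos[0] - placed(m, 0), dy = pos[1] - placed(m, 1),
             dz = pos[2] - placed(m, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rcut2) continue;
      if (r2 < 1e-18) return R_PosInf;
      double r = std::sqrt(r2);
      if (ke != 0.0)
        u += ke * charges[j] * charges[m] * std::exp(-kappa * r) / r;
      double sr6 = std::pow(sigma0 * sigma0 / r2, 3.0);
      u += kev * (sr6 * sr6 - sr6);
    }
    if (j >= 1) {                        // bending at the previous joint
      double ax, ay, az;
      if (j == 1) { ax = attach[0]; ay = attach[1]; az = attach[2]; }
      else { ax = placed(j - 2, 0); ay = placed(j - 2, 1); az = placed(j - 2, 2); }
      double u1x = placed(j - 1, 0) - ax, u1y = placed(j - 1, 1) - ay,
             u1z = placed(j - 1, 2) - az;
      double u2x = pos[0] - placed(j - 1, 0), u2y = pos[1] - placed(j - 1, 1),
             u2z = pos[2] - placed(j - 1, 2);
      double cang = (u1x * u2x + u1y * u2y + u1z * u2z) /
        std::sqrt((u1x * u1x + u1y * u1y + u1z * u1z) *
                  (u2x * u2x + u2y * u2y + u2z * u2z));
      if (cang > 1) cang = 1;
      if (cang < -1) cang = -1;
      double th = std::acos(cang);
      u += 0.5 * g_eff * th * th;
    }
    return u;
  };

  auto grow = [&](bool retrace, NumericMatrix& out) {
    double W_log = 0.0;
    for (int j = 0; j < nb; ++j) {
      double prev[3];
      if (j == 0) { prev[0] = attach[0]; prev[1] = attach[1]; prev[2] = attach[2]; }
      else { prev[0] = out(j - 1, 0); prev[1] = out(j - 1, 1); prev[2] = out(j - 1, 2); }
      int first = retrace ? 1 : 0;
      if (retrace) {
        trials[0] = old_pos(j, 0); trials[1] = old_pos(j, 1);
        trials[2] = old_pos(j, 2);
        us[0] = bead_u(&trials[0], out, j);
      }
      for (int t = first; t < ntr; ++t) {
        double l = sample_bond(l0t, h_eff, kBT);
        double dir[3];
        rand_unit_vec(dir);
        trials[3 * t] = prev[0] + l * dir[0];
        trials[3 * t + 1] = prev[1] + l * dir[1];
        trials[3 * t + 2] = prev[2] + l * dir[2];
        us[t] = bead_u(&trials[3 * t], out, j);
      }
      double wsum = 0.0;
      for (int t = 0; t < ntr; ++t) {
        double u = us[t];
        if (u > 500.0 * kBT) u = 500.0 * kBT;
        wts[t] = std::exp(-beta * u);
        wsum += wts[t];
      }
      if (!(wsum > 0) || !std::isfinite(wsum)) return R_NegInf;
      W_log += std::log(wsum / ntr);
      int sel = 0;
      if (!retrace) {
        double pick = unif_rand() * wsum, cum = 0.0;
        sel = ntr - 1;
        for (int t = 0; t < ntr; ++t) {
          cum += wts[t];
          if (pick <= cum) { sel = t; break; }
        }
      }
      out(j, 0) = trials[3 * sel];
      out(j, 1) = trials[3 * sel + 1];
      out(j, 2) = trials[3 * sel + 2];
    }
    return W_log;
  };

  double W_new = grow(false, grown);
  NumericMatrix retr(nb, 3);
  double W_old = (W_new == R_NegInf) ? R_NegInf : grow(true, retr);
  double logratio = (W_new == R_NegInf || W_old == R_NegInf)
    ? R_NegInf : W_new - W_old;
  return List::create(_["logratio"] = logratio, _["pos"] = grown);
}

// In-place rigid transform x -> R (x - center) + center + shift of the
// given rows (1-based) of P. The caller owns P exclusively (snapshots are
// deep-copied before any in-place update).
// [[Rcpp::export]]
void transform_rows_cpp(NumericMatrix P, IntegerVector rows, NumericMatrix R,
                        NumericVector center, NumericVector shift) {
  for (int k = 0; k < rows.size(); ++k) {
    int i = rows[k] - 1;
    double x = P(i, 0) - center[0], y = P(i, 1) - center[1],
           z = P(i, 2) - center[2];
    P(i, 0) = R(0, 0) * x + R(0, 1) * y + R(0, 2) * z + center[0] + shift[0];
    P(i, 1) = R(1, 0) * x + R(1, 1) * y + R(1, 2) * z + center[1] + shift[1];
    P(i, 2) = R(2, 0) * x + R(2, 1) * y + R(2, 2) * z + center[2] + shift[2];
  }
}

// Same transform, returning the new coordinates without touching P.
// [[Rcpp::export]]
NumericMatrix preview_rows_cpp(NumericMatrix P, IntegerVector rows,
                               NumericMatrix R, NumericVector center,
                               NumericVector shift) {
  NumericMatrix out(rows.size(), 3);
  for (int k = 0; k < rows.size(); ++k) {
    int i = rows[k] - 1;
    double x = P(i, 0) - center[0], y = P(i, 1) - center[1],
           z = P(i, 2) - center[2];
    out(k, 0) = R(0, 0) * x + R(0, 1) * y + R(0, 2) * z + center[0] + shift[0];
    out(k, 1) = R(1, 0) * x + R(1, 1) * y + R(1, 2) * z + center[1] + shift[1];
    out(k, 2) = R(2, 0) * x + R(2, 1) * y + R(2, 2) * z + center[2] + shift[2];
  }
  return out;
}

// In-place row assignment P[rows, ] <- V.
// [[Rcpp::export]]
void set_rows_cpp(NumericMatrix P, IntegerVector rows, NumericMatrix V) {
  for (int k = 0; k < rows.size(); ++k) {
    int i = rows[k] - 1;
    P(i, 0) = V(k, 0);
    P(i, 1) = V(k, 1);
    P(i, 2) = V(k, 2);
  }
}

// All element pairs closer than rcut (1-based indices), regardless of
// activity or exclusions; used by the contact analysis where folded tails
// still occupy space.
// [[Rcpp::export]]
IntegerMatrix pairs_within_cpp(NumericMatrix P, double rcut) {
  int n = P.nrow();
  std::vector<int> ids(n);
  for (int i = 0; i < n; ++i) ids[i] = i;
  CellIndex ci;
  ci.build(P, ids, rcut);
  double rcut2 = rcut * rcut;
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    ci.neighbors(P(i, 0), P(i, 1), P(i, 2), [&](int j) {
      if (j <= i) return;
      double dx = P(i, 0) - P(j, 0), dy = P(i, 1) - P(j, 1),
             dz = P(i, 2) - P(j, 2);
      if (dx * dx + dy * dy + dz * dz < rcut2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
    });
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}

// Minimum element-element distance for every nucleosome pair (groups are
// 1-based nucleosome assignments; 0 = unassigned). Returns an N x N matrix
// of minimal distances (Inf where no pair is within `horizon`).
// [[Rcpp::export]]
NumericMatrix group_contacts_cpp(NumericMatrix P, IntegerVector group,
                                 int n_groups, double horizon) {
  int n = P.nrow();
  std::vector<int> ids;
  ids.reserve(n);
  for (int i = 0; i < n; ++i)
    if (group[i] > 0) ids.push_back(i);
  CellIndex ci;
  ci.build(P, ids, horizon);
  NumericMatrix out(n_groups, n_groups);
  std::fill(out.begin(), out.end(), R_PosInf);
  double h2 = horizon * horizon;
  for (int i : ids) {
    int gi = group[i];
    ci.neighbors(P(i, 0), P(i, 1), P(i, 2), [&](int j) {
      if (j <= i) return;
      int gj = group[j];
      if (gj == gi) return;
      double dx = P(i, 0) - P(j, 0), dy = P(i, 1) - P(j, 1),
             dz = P(i, 2) - P(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= h2) return;
      double r = std::sqrt(r2);
      if (r < out(gi - 1, gj - 1)) {
        out(gi - 1, gj - 1) = r;
        out(gj - 1, gi - 1) = r;
      }
    });
  }
  return out;
}
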