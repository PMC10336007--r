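// Bead-spring polymer force evaluation and BAOAB Langevin integration.
// All quantities in reduced units: lengths in sigma, energies in kBT, mass 1.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Per-pair force magnitudes are capped at FORCE_CAP (regularizes r -> 0
// overlaps of steep pair terms; capped events are counted and reported).
static const double FORCE_CAP = 1.0e4;
static const double R_MIN = 1.0e-9;

enum PairType { PAIR_NONE = 0, PAIR_WCA = 1, PAIR_LJ = 2, PAIR_TAB = 3 };

struct PairParams {
  int type;
  double eps, sigma, rcut;
  // tabulated term: cubic Hermite interpolation on a strictly increasing grid
  std::vector<double> tr, tv, tm; // grid, values, node slopes
  double tmax;
};

// Cubic Hermite evaluation of V(r) and dV/dr on the tabulated grid.
// Beyond the last grid point the potential (and force) is zero.
static inline void tab_eval(const PairParams &pp, double r, double &v, double &dv) {
  const std::vector<double> &g = pp.tr;
  if (r >= pp.tmax || g.size() < 2) { v = 0.0; dv = 0.0; return; }
  if (r <= g.front()) r = g.front();
  size_t hi = std::upper_bound(g.begin(), g.end(), r) - g.begin();
  if (hi >= g.size()) hi = g.size() - 1;
  if (hi == 0) hi = 1;
  size_t lo = hi - 1;
  double h = g[hi] - g[lo];
  double t = (r - g[lo]) / h;
  double t2 = t * t, t3 = t2 * t;
  double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + t;
  double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
  v = h00 * pp.tv[lo] + h10 * h * pp.tm[lo] + h01 * pp.tv[hi] + h11 * h * pp.tm[hi];
  double d00 = 6 * t2 - 6 * t, d10 = 3 * t2 - 4 * t + 1;
  double d01 = -6 * t2 + 6 * t, d11 = 3 * t2 - 2 * t;
  dv = (d00 * pp.tv[lo] + d01 * pp.tv[hi]) / h + d10 * pp.tm[lo] + d11 * pp.tm[hi];
}

// Pair potential value and magnitude of dV/dr at separation r.
static inline void pair_eval(const PairParams &pp, double r, double &v, double &dv) {
  v = 0.0; dv = 0.0;
  if (pp.type == PAIR_NONE) return;
  if (pp.type == PAIR_TAB) { tab_eval(pp, r, v, dv); return; }
  if (r >= pp.rcut) return;
  double sr = pp.sigma / r;
  double sr6 = sr * sr * sr; sr6 *= sr6;
  double sr12 = sr6 * sr6;
  v = 4.0 * pp.eps * (sr12 - sr6);
  dv = -24.0 * pp.eps * (2.0 * sr12 - sr6) / r;
  if (pp.type == PAIR_WCA) {
    v += pp.eps; // truncated-and-shifted at the minimum 2^(1/6) sigma
  } else {
    double src = pp.sigma / pp.rcut;
    double src6 = src * src * src; src6 *= src6;
    v -= 4.0 * pp.eps * (src6 * src6 - src6); // truncated-and-shifted LJ
  }
}

// interaction range of the pair term (cell edge for the neighbor search)
static inline double pair_range(const PairParams &pp) {
  if (pp.type == PAIR_TAB) return pp.tmax;
  return pp.rcut;
}

struct FFParams {
  double chain_k, chain_r0;
  std::vector<int> bi, bj;           // constraint bonds, 0-based
  std::vector<double> bk, br0;
  PairParams pair;
};

static FFParams unpack_ff(double chain_k, double chain_r0,
                          IntegerMatrix cbonds, NumericVector cbond_k,
                          NumericVector cbond_r0, int pair_type,
                          double pair_eps, double pair_sigma, double pair_rcut,
                          NumericVector tab_r, NumericVector tab_v,
                          NumericVector tab_m) {
  FFParams ff;
  ff.chain_k = chain_k; ff.chain_r0 = chain_r0;
  int m = cbonds.nrow();
  ff.bi.resize(m); ff.bj.resize(m); ff.bk.resize(m); ff.br0.resize(m);
  for (int b = 0; b < m; ++b) {
    ff.bi[b] = cbonds(b, 0); ff.bj[b] = cbonds(b, 1);
    ff.bk[b] = cbond_k[b];   ff.br0[b] = cbond_r0[b];
  }
  ff.pair.type = pair_type;
  ff.pair.eps = pair_eps; ff.pair.sigma = pair_sigma; ff.pair.rcut = pair_rcut;
  if (pair_type == PAIR_TAB) {
    ff.pair.tr.assign(tab_r.begin(), tab_r.end());
    ff.pair.tv.assign(tab_v.begin(), tab_v.end());
    ff.pair.tm.assign(tab_m.begin(), tab_m.end());
    ff.pair.tmax = ff.pair.tr.back();
  }
  return ff;
}

// Total potential energy and per-bead forces (negative gradient).
static double compute_forces(const std::vector<double> &x, int n,
                             const FFParams &ff, std::vector<double> &f,
                             long &n_capped) {
  std::fill(f.begin(), f.end(), 0.0);
  double e = 0.0;

  auto add_spring = [&](int i, int j, double k, double r0) {
    double dx = x[3 * j] - x[3 * i];
    double dy = x[3 * j + 1] - x[3 * i + 1];
    double dz = x[3 * j + 2] - x[3 * i + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < R_MIN) r = R_MIN;
    e += 0.5 * k * (r - r0) * (r - r0);
    double fmag = -k * (r - r0); // along +rij acting on j
    double fx = fmag * dx / r, fy = fmag * dy / r, fz = fmag * dz / r;
    f[3 * j] += fx; f[3 * j + 1] += fy; f[3 * j + 2] += fz;
    f[3 * i] -= fx; f[3 * i + 1] -= fy; f[3 * i + 2] -= fz;
  };

  for (int i = 0; i + 1 < n; ++i) add_spring(i, i + 1, ff.chain_k, ff.chain_r0);
  for (size_t b = 0; b < ff.bi.size(); ++b)
    add_spring(ff.bi[b], ff.bj[b], ff.bk[b], ff.br0[b]);

  if (ff.pair.type != PAIR_NONE) {
    double rc = pair_range(ff.pair);
    double rc2 = rc * rc;

    auto pair_interact = [&](int i, int j) {
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) return;
      double r = std::sqrt(r2);
      if (r < R_MIN) r = R_MIN;
      double v, dv;
      pair_eval(ff.pair, r, v, dv);
      if (v == 0.0 && dv == 0.0) return;
      e += v;
      double fmag = -dv; // repulsive dv<0 -> positive push along rij
      if (std::fabs(fmag) > FORCE_CAP) {
        fmag = (fmag > 0 ? FORCE_CAP : -FORCE_CAP);
        ++n_capped;
      }
      double fx = fmag * dx / r, fy = fmag * dy / r, fz = fmag * dz / r;
      f[3 * j] += fx; f[3 * j + 1] += fy; f[3 * j + 2] += fz;
      f[3 * i] -= fx; f[3 * i + 1] -= fy; f[3 * i + 2] -= fz;
    };

    // linked-cell neighbor search with cell edge >= interaction range;
    // falls back to the all-pairs loop for small N
    if (n < 64) {
      for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j) pair_interact(i, j);
    } else {
      double lo[3], hi[3];
      for (int d = 0; d < 3; ++d) { lo[d] = x[d]; hi[d] = x[d]; }
      for (int i = 1; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          lo[d] = std::min(lo[d], x[3 * i + d]);
          hi[d] = std::max(hi[d], x[3 * i + d]);
        }
      int dim[3];
      for (int d = 0; d < 3; ++d) {
        dim[d] = std::max(1, std::min(64, (int)((hi[d] - lo[d]) / rc) + 1));
      }
      int n_cells = dim[0] * dim[1] * dim[2];
      std::vector<int> head(n_cells, -1), nxt(n, -1), cell_of(n);
      auto cell_index = [&](int i, int cix[3]) {
        for (int d = 0; d < 3; ++d) {
          int c = (int)((x[3 * i + d] - lo[d]) / rc);
          cix[d] = std::max(0, std::min(dim[d] - 1, c));
        }
        return cix[0] + dim[0] * (cix[1] + dim[1] * cix[2]);
      };
      int cix[3];
      for (int i = 0; i < n; ++i) {
        int c = cell_index(i, cix);
        cell_of[i] = c;
        nxt[i] = head[c];
        head[c] = i;
      }
      for (int i = 0; i < n; ++i) {
        cell_index(i, cix);
        for (int dz = -1; dz <= 1; ++dz) {
          int cz = cix[2] + dz;
          if (cz < 0 || cz >= dim[2]) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int cy = cix[1] + dy;
            if (cy < 0 || cy >= dim[1]) continue;
            for (int dxc = -1; dxc <= 1; ++dxc) {
              int cx = cix[0] + dxc;
              if (cx < 0 || cx >= dim[0]) continue;
              int c = cx + dim[0] * (cy + dim[1] * cz);
              for (int j = head[c]; j != -1; j = nxt[j]) {
                if (j <= i) continue;
                pair_interact(i, j);
              }
            }
          }
        }
      }
    }
  }
  return e;
}

// [[Rcpp::export]]
List eval_forces_cpp(NumericMatrix coords, double chain_k, double chain_r0,
                     IntegerMatrix cbonds, NumericVector cbond_k,
                     NumericVector cbond_r0, int pair_type, double pair_eps,
                     double pair_sigma, double pair_rcut, NumericVector tab_r,
                     NumericVector tab_v, NumericVector tab_m) {
  int n = coords.nrow();
  FFParams ff = unpack_ff(chain_k, chain_r0, cbonds, cbond_k, cbond_r0,
                          pair_type, pair_eps, pair_sigma, pair_rcut,
                          tab_r, tab_v, tab_m);
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  long n_capped = 0;
  double e = compute_forces(x, n, ff, f, n_capped);
  NumericMatrix fm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fm(i, d) = f[3 * i + d];
  return List::create(_["energy"] = e, _["forces"] = fm,
                      _["n_capped"] = (double)n_capped);
}

static double rg_of(const std::vector<double> &x, int n) {
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += x[3*i]; cy += x[3*i+1]; cz += x[3*i+2]; }
  cx /= n; cy /= n; cz /= n;
  double s = 0;
  for (int i = 0; i < n; ++i) {
    double dx = x[3*i] - cx, dy = x[3*i+1] - cy, dz = x[3*i+2] - cz;
    s += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(s / n);
}

// BAOAB discretization of Langevin dynamics at temperature `temp` (kBT),
// unit mass, friction gamma. Deterministic given `seed`.
// [[Rcpp::export]]
List run_langevin_cpp(NumericMatrix coords, double chain_k, double chain_r0,
                      IntegerMatrix cbonds, NumericVector cbond_k,
                      NumericVector cbond_r0, int pair_type, double pair_eps,
                      double pair_sigma, double pair_rcut, NumericVector tab_r,
                      NumericVector tab_v, NumericVector tab_m, double dt,
                      double gamma, double temp, int n_steps, int sample_every,
                      double seed) {
  int n = coords.nrow();
  FFParams ff = unpack_ff(chain_k, chain_r0, cbonds, cbond_k, cbond_r0,
                          pair_type, pair_eps, pair_sigma, pair_rcut,
                          tab_r, tab_v, tab_m);
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  double vscale = std::sqrt(temp);
  for (int i = 0; i < 3 * n; ++i) v[i] = vscale * norm(rng);

  long n_capped = 0;
  double epot = compute_forces(x, n, ff, f, n_capped);

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, (1.0 - c1 * c1) * temp));

  int n_rec = n_steps / sample_every;
  NumericVector rec_rg(n_rec), rec_epot(n_rec), rec_ekin(n_rec);
  // samples stored as an (n_rec x n x 3) array, filled slice by slice
  NumericVector samples(Dimension(n_rec, n, 3));

  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];      // B
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];      // A
    for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * norm(rng); // O
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];      // A
    epot = compute_forces(x, n, ff, f, n_capped);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];      // B

    if (step % sample_every == 0) {
      for (int i = 0; i < 3 * n; ++i)
        if (!std::isfinite(x[i]))
          stop("coordinates diverged (NaN/Inf) at step %d", step);
      double ekin = 0;
      for (int i = 0; i < 3 * n; ++i) ekin += 0.5 * v[i] * v[i];
      rec_rg[rec] = rg_of(x, n);
      rec_epot[rec] = epot;
      rec_ekin[rec] = ekin;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          samples[rec + n_rec * (i + n * d)] = x[3 * i + d];
      ++rec;
    }
  }
  return List::create(_["samples"] = samples, _["rg"] = rec_rg,
                      _["epot"] = rec_epot, _["ekin"] = rec_ekin,
                      _["n_capped"] = (double)n_capped);
}

// Histogram of distances between bead pairs with |i-j| >= min_sep, pooled
// over the conformations of an ensemble. coords_list: list of N x 3 matrices.
// [[Rcpp::export]]
NumericVector pair_distance_hist_cpp(List coords_list, int min_sep,
                                     NumericVector breaks) {
  int nb = breaks.size() - 1;
  NumericVector counts(nb);
  double lo = breaks[0], hi = breaks[nb];
  double w = (hi - lo) / nb; // uniform breaks assumed
  for (int c = 0; c < coords_list.size(); ++c) {
    NumericMatrix m = coords_list[c];
    int n = m.nrow();
    for (int i = 0; i < n - min_sep; ++i) {
      for (int j = i + min_sep; j < n; ++j) {
        double dx = m(j,0) - m(i,0), dy = m(j,1) - m(i,1), dz = m(j,2) - m(i,2);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < lo || r >= hi) continue;
        int b = (int)((r - lo) / w);
        if (b >= 0 && b < nb) counts[b] += 1.0;
      }
    }
  }
  return counts;
}

// Fraction of (conformation, pair) events with r_ij < cutoff, per pair.
// Returns an n x n symmetric matrix of counts.
// [[Rcpp::export]]
NumericMatrix contact_count_cpp(List coords_list, double cutoff) {
  NumericMatrix first = coords_list[0];
  int n = first.nrow();
  NumericMatrix counts(n, n);
  double c2 = cutoff * cutoff;
  for (int c = 0; c < coords_list.size(); ++c) {
    NumericMatrix m = coords_list[c];
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = m(j,0) - m(i,0), dy = m(j,1) - m(i,1), dz = m(j,2) - m(i,2);
        if (dx * dx + dy * dy + dz * dz < c2) {
          counts(i, j) += 1.0; counts(j, i) += 1.0;
        }
      }
    }
  }
  return counts;
}
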