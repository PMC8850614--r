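// Core simulation kernels: cell-list proximity search, union-find clustering,
// and the coupled Euler-Maruyama / synchronous-SIR time loop.
//
// Conventions (shared with the R level):
//   positions live in [0, L)^2, headings in [-pi, pi);
//   an edge exists iff the minimum-image distance is <= r_int (inclusive);
//   sir codes: 0 = S, 1 = I, 2 = R.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

// positive modulo via floor (avoids fmod)
static inline double pmod(double x, double m) {
  double y = x - m * std::floor(x / m);
  if (y < 0.0) y += m;
  if (y >= m) y -= m;
  return y;
}

static inline double wrap_angle_c(double x) {
  // mod*(x) = mod(x + pi, 2 pi) - pi, result in [-pi, pi)
  double y = pmod(x + M_PI, 2.0 * M_PI) - M_PI;
  if (y >= M_PI) y = -M_PI;  // guard rounding at the seam
  return y;
}

static inline double wrap_pos_c(double x, double L) {
  return pmod(x, L);
}

static inline double min_image_c(double d, double L) {
  // shift d by multiples of L into [-L/2, L/2)
  return pmod(d + 0.5 * L, L) - 0.5 * L;
}

// fast variants for the hot loops: valid for |d| < 1.5 L (positions are
// already wrapped, so coordinate differences lie in (-L, L)), with the exact
// pmod fallback when the precondition could fail
static inline double mi_fast(double d, double L) {
  if (d >= 0.5 * L) return d - L;
  if (d < -0.5 * L) return d + L;
  return d;
}
static inline double wrap_angle_fast(double x) {
  // input in (-2 pi, 2 pi): one correction suffices
  if (x >= M_PI) return x - 2.0 * M_PI;
  if (x < -M_PI) return x + 2.0 * M_PI;
  return x;
}
static inline double wrap_pos_fast(double x, double L) {
  if (x >= L) { x -= L; if (x >= L) return pmod(x, L); return x; }
  if (x < 0.0) { x += L; if (x < 0.0) return pmod(x, L); return x; }
  return x;
}

// splitmix64: expands a small integer seed into well-mixed 64-bit engine seeds
static inline std::uint64_t splitmix64(std::uint64_t &s) {
  std::uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static std::mt19937_64 make_engine(double seed) {
  std::uint64_t s = static_cast<std::uint64_t>(seed);
  std::uint64_t a = splitmix64(s);
  return std::mt19937_64(a);
}

// ---------------------------------------------------------------------------
// pair search

struct PairList {
  std::vector<int> i, j;
  std::vector<double> d;
  void clear() { i.clear(); j.clear(); d.clear(); }
  void push(int a, int b, double dist) {
    i.push_back(a); j.push_back(b); d.push_back(dist);
  }
};

static void pairs_brute(const std::vector<double> &x, const std::vector<double> &y,
                        double L, double r_int, PairList &out) {
  const int n = (int)x.size();
  const double r2 = r_int * r_int;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      double dx = mi_fast(x[a] - x[b], L);
      double dy = mi_fast(y[a] - y[b], L);
      double d2 = dx * dx + dy * dy;
      if (d2 <= r2) out.push(a, b, std::sqrt(d2));
    }
}

// cell list with cell size >= r_int; exact (set-identical to brute force)
static void pairs_cell(const std::vector<double> &x, const std::vector<double> &y,
                       double L, double r_int, PairList &out,
                       std::vector<int> &head, std::vector<int> &nxt) {
  const int n = (int)x.size();
  int nc = (int)std::floor(L / r_int);
  // bound the grid to O(n) cells: very dilute boxes would otherwise ask for
  // (L/r_int)^2 cells; larger cells stay exact (cell >= r_int keeps the
  // one-ring stencil), only the candidate count grows
  int nc_cap = 2 * (int)std::ceil(std::sqrt((double)n)) + 1;
  if (nc > nc_cap) nc = nc_cap;
  if (nc < 4) { pairs_brute(x, y, L, r_int, out); return; }
  const double cell = L / nc;
  const double r2 = r_int * r_int;
  head.assign((size_t)nc * nc, -1);
  nxt.assign(n, -1);
  for (int a = 0; a < n; ++a) {
    int ix = (int)(x[a] / cell); if (ix >= nc) ix = nc - 1;
    int iy = (int)(y[a] / cell); if (iy >= nc) iy = nc - 1;
    int c = iy * nc + ix;
    nxt[a] = head[c];
    head[c] = a;
  }
  // half-neighbourhood stencil: self + 4 cells, each pair visited once
  const int sx[5] = {0, 1, 1, 0, -1};
  const int sy[5] = {0, 0, 1, 1, 1};
  for (int iy = 0; iy < nc; ++iy) {
    for (int ix = 0; ix < nc; ++ix) {
      int c0 = iy * nc + ix;
      if (head[c0] == -1) continue; // empty cell: nothing to pair
      for (int s = 0; s < 5; ++s) {
        int jx = (ix + sx[s] + nc) % nc;
        int jy = (iy + sy[s] + nc) % nc;
        int c1 = jy * nc + jx;
        for (int a = head[c0]; a != -1; a = nxt[a]) {
          int bstart = (s == 0) ? nxt[a] : head[c1];
          for (int b = bstart; b != -1; b = nxt[b]) {
            double dx = mi_fast(x[a] - x[b], L);
            double dy = mi_fast(y[a] - y[b], L);
            double d2 = dx * dx + dy * dy;
            if (d2 <= r2) {
              if (a < b) out.push(a, b, std::sqrt(d2));
              else       out.push(b, a, std::sqrt(d2));
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_contact_pairs(NumericVector x, NumericVector y, double L, double r_int) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  PairList pl;
  std::vector<int> head, nxt;
  pairs_cell(xv, yv, L, r_int, pl, head, nxt);
  const int m = (int)pl.i.size();
  IntegerVector ii(m), jj(m);
  NumericVector dd(m);
  for (int k = 0; k < m; ++k) {
    ii[k] = pl.i[k] + 1; jj[k] = pl.j[k] + 1; dd[k] = pl.d[k];
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["dist"] = dd);
}

// ---------------------------------------------------------------------------
// union-find largest component

struct UnionFind {
  std::vector<int> parent, size;
  void init(int n) {
    parent.resize(n); size.assign(n, 1);
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a; size[a] += size[b];
  }
  int largest() const {
    int m = 0;
    for (size_t i = 0; i < parent.size(); ++i)
      if (parent[i] == (int)i && size[i] > m) m = size[i];
    return m;
  }
};

static double largest_cluster_frac(const PairList &pl, int n, UnionFind &uf) {
  uf.init(n);
  for (size_t k = 0; k < pl.i.size(); ++k) uf.unite(pl.i[k], pl.j[k]);
  return (double)uf.largest() / (double)n;
}

// [[Rcpp::export]]
double cpp_largest_component_fraction(IntegerVector i, IntegerVector j, int n) {
  UnionFind uf; uf.init(n);
  for (int k = 0; k < i.size(); ++k) uf.unite(i[k] - 1, j[k] - 1);
  return (double)uf.largest() / (double)n;
}

// ---------------------------------------------------------------------------
// main loop

static double polarization_c(const std::vector<double> &th) {
  double cs = 0.0, sn = 0.0;
  for (double t : th) { cs += std::cos(t); sn += std::sin(t); }
  const double n = (double)th.size();
  return std::sqrt(cs * cs + sn * sn) / n;
}

// Coupled spatial + contagion run.  One iteration:
//   1. contact pairs from current positions;
//   2. synchronous SIR transitions evaluated on the pre-step state (if enabled);
//   3. Euler-Maruyama update of headings and positions from the pre-step state.
// Spatial, infection and recovery randomness use independent engines so the
// spatial trajectory is bit-identical under any change of epidemic parameters.
// [[Rcpp::export]]
List cpp_simulate(NumericVector x0, NumericVector y0, NumericVector theta0,
                  IntegerVector sir0,
                  double v0, double r_int, double sigma, double tau,
                  double L, double dt, int n_steps,
                  bool contagion, double beta_b, double gamma,
                  double seed_spatial, double seed_infect, double seed_recover,
                  int record_every, bool stop_when_extinct, double t0) {
  const int n = x0.size();
  if (n < 1) stop("empty state");
  if (r_int >= L / 2.0) stop("r_int must be < L/2 (minimum-image ambiguity)");
  if (dt <= 0.0) stop("dt must be positive");
  if (contagion && gamma * dt >= 1.0)
    stop("gamma*dt >= 1: integration step too coarse for recovery");

  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end()),
      th(theta0.begin(), theta0.end());
  std::vector<int> sir(sir0.begin(), sir0.end());
  for (int a = 0; a < n; ++a) {
    if (!std::isfinite(x[a]) || !std::isfinite(y[a]) || !std::isfinite(th[a]))
      stop("non-finite particle state at entry");
    x[a] = wrap_pos_c(x[a], L);
    y[a] = wrap_pos_c(y[a], L);
    th[a] = wrap_angle_c(th[a]);
  }

  std::mt19937_64 eng_sp = make_engine(seed_spatial);
  std::mt19937_64 eng_inf = make_engine(seed_infect);
  std::mt19937_64 eng_rec = make_engine(seed_recover);
  std::normal_distribution<double> rnorm01(0.0, 1.0);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);

  PairList pl;
  std::vector<int> head, nxt, kinf(n), mark(n);
  std::vector<double> asum(n), fx(n), fy(n);
  std::vector<int> acnt(n);
  UnionFind uf;

  int nS = 0, nI = 0, nR = 0;
  for (int a = 0; a < n; ++a) {
    if (sir[a] == 0) ++nS; else if (sir[a] == 1) ++nI; else ++nR;
  }
  int peak_nI = nI;
  long n_capped = 0, n_warn = 0;

  std::vector<double> rec_t, rec_phi, rec_lam;
  std::vector<int> rec_S, rec_I, rec_R;
  const double sqrtdt = std::sqrt(dt);
  const double noise_amp = sigma * sqrtdt;

  // record a frame from the current state (rebuilds pairs for Lambda)
  auto record = [&](double tnow) {
    pl.clear();
    pairs_cell(x, y, L, r_int, pl, head, nxt);
    rec_t.push_back(tnow);
    rec_S.push_back(nS); rec_I.push_back(nI); rec_R.push_back(nR);
    rec_phi.push_back(polarization_c(th));
    rec_lam.push_back(largest_cluster_frac(pl, n, uf));
  };

  record(t0);

  // Verlet-skin neighbor list: candidate pairs are gathered once with radius
  // r_int + skin and filtered exactly every step; the candidate list stays
  // valid while no pair separation can have shrunk by more than the skin,
  // i.e. while twice the accumulated maximum per-step displacement is below
  // it. The per-step contact graph is identical to a fresh build.
  double skin = 0.3 * r_int;
  if (r_int + skin >= L / 2.0) skin = 0.0;
  PairList pad;
  double skin_used = 2.0 * skin; // force a build on the first step

  int steps_done = 0;
  bool extinct = contagion && nI == 0;
  for (int step = 0; step < n_steps && !(extinct && stop_when_extinct); ++step) {
    if (skin_used >= skin) {
      pad.clear();
      pairs_cell(x, y, L, r_int + skin, pad, head, nxt);
      skin_used = 0.0;
    }
    pl.clear();
    if (skin > 0.0) {
      const double r2 = r_int * r_int;
      for (size_t k = 0; k < pad.i.size(); ++k) {
        int a = pad.i[k], b = pad.j[k];
        double dx = mi_fast(x[a] - x[b], L);
        double dy = mi_fast(y[a] - y[b], L);
        double d2 = dx * dx + dy * dy;
        if (d2 <= r2) pl.push(a, b, std::sqrt(d2));
      }
    } else {
      std::swap(pl, pad);
      skin_used = 2.0 * skin; // unpadded list: rebuild next step
    }
    const int m = (int)pl.i.size();

    // --- contagion (synchronous, pre-step state) ---
    if (contagion && nI > 0) {
      std::fill(kinf.begin(), kinf.end(), 0);
      for (int k = 0; k < m; ++k) {
        int a = pl.i[k], b = pl.j[k];
        if (sir[a] == 1 && sir[b] == 0) ++kinf[b];
        if (sir[b] == 1 && sir[a] == 0) ++kinf[a];
      }
      std::fill(mark.begin(), mark.end(), 0);
      for (int a = 0; a < n; ++a) {
        if (sir[a] == 0 && kinf[a] > 0) {
          double p = kinf[a] * beta_b * dt;
          if (p > 0.1) ++n_warn;
          if (p > 1.0) { p = 1.0; ++n_capped; }
          if (runif01(eng_inf) < p) mark[a] = 1;  // S -> I
        }
      }
      const double prec = gamma * dt;
      for (int a = 0; a < n; ++a)
        if (sir[a] == 1 && runif01(eng_rec) < prec) mark[a] = 2;  // I -> R
      for (int a = 0; a < n; ++a) {
        if (mark[a] == 1) { sir[a] = 1; --nS; ++nI; }
        else if (mark[a] == 2) { sir[a] = 2; --nI; ++nR; }
      }
      if (nI > peak_nI) peak_nI = nI;
      if (nI == 0) extinct = true;
    }

    // --- spatial interactions from the pre-step state ---
    std::fill(asum.begin(), asum.end(), 0.0);
    std::fill(acnt.begin(), acnt.end(), 0);
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    for (int k = 0; k < m; ++k) {
      int a = pl.i[k], b = pl.j[k];
      double w = wrap_angle_fast(th[b] - th[a]);
      asum[a] += w; ++acnt[a];
      asum[b] += wrap_angle_fast(th[a] - th[b]); ++acnt[b];
      double d = pl.d[k];
      if (d > 0.0) {
        double f = (r_int - d) / r_int;
        double ux = mi_fast(x[a] - x[b], L) / d;
        double uy = mi_fast(y[a] - y[b], L) / d;
        fx[a] += f * ux; fy[a] += f * uy;
        fx[b] -= f * ux; fy[b] -= f * uy;
      } else {
        // coincident particles: repulsion direction undefined, draw one
        double ang = (2.0 * runif01(eng_sp) - 1.0) * M_PI;
        fx[a] += std::cos(ang); fy[a] += std::sin(ang);
        fx[b] -= std::cos(ang); fy[b] -= std::sin(ang);
      }
    }

    // --- Euler-Maruyama update ---
    double max_v2 = 0.0;
    for (int a = 0; a < n; ++a) {
      // the interaction set includes the focal agent (its own wrapped
      // difference is zero, but it counts in the divisor)
      double align = (acnt[a] > 0) ? asum[a] / ((acnt[a] + 1) * tau) : 0.0;
      double xi = rnorm01(eng_sp);
      double vx = v0 * std::cos(th[a]) + fx[a];
      double vy = v0 * std::sin(th[a]) + fy[a];
      double v2 = vx * vx + vy * vy;
      if (v2 > max_v2) max_v2 = v2;
      x[a] = wrap_pos_fast(x[a] + vx * dt, L);
      y[a] = wrap_pos_fast(y[a] + vy * dt, L);
      double thn = th[a] + align * dt + noise_amp * xi;
      th[a] = (thn >= M_PI || thn < -M_PI) ? wrap_angle_c(thn) : thn;
    }
    skin_used += 2.0 * std::sqrt(max_v2) * dt;

    ++steps_done;
    bool last = (step == n_steps - 1) || (extinct && stop_when_extinct);
    if (steps_done % record_every == 0 || last) {
      if (!std::isfinite(x[0]) || !std::isfinite(th[0]))
        stop("non-finite state encountered during integration");
      record(t0 + steps_done * dt);
    }
  }

  NumericMatrix series((int)rec_t.size(), 6);
  colnames(series) = CharacterVector::create("t", "n_s", "n_i", "n_r", "phi", "lambda");
  for (int k = 0; k < (int)rec_t.size(); ++k) {
    series(k, 0) = rec_t[k];
    series(k, 1) = rec_S[k];
    series(k, 2) = rec_I[k];
    series(k, 3) = rec_R[k];
    series(k, 4) = rec_phi[k];
    series(k, 5) = rec_lam[k];
  }

  return List::create(
      _["x"] = NumericVector(x.begin(), x.end()),
      _["y"] = NumericVector(y.begin(), y.end()),
      _["theta"] = NumericVector(th.begin(), th.end()),
      _["sir"] = IntegerVector(sir.begin(), sir.end()),
      _["t_end"] = t0 + steps_done * dt,
      _["steps_done"] = steps_done,
      _["extinct"] = extinct,
      _["n_s"] = nS, _["n_i"] = nI, _["n_r"] = nR,
      _["peak_n_i"] = peak_nI,
      _["n_capped"] = (double)n_capped,
      _["n_linear_warn"] = (double)n_warn,
      _["series"] = series);
}
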