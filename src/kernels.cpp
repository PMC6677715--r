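// Event-driven stochastic kernels: per-cell direct-method SSA for the
// Notch-Delta-Reporter transitions and the Next Subvolume Method for the
// voxelized single-cell model. Channel order (fixed; trajectories are
// seed-reproducible only because this order never changes):
//   1 0 -> N        rate beta_n * Omega
//   2 0 -> D        rate beta_d * Omega * r1,  r1 = 1/(1 + (R/Omega)^m)
//   3 0 -> R        rate beta_r * Omega * r2,
//                    r2 = u^s/(k_rs + u^s), u = <D_out> N / Omega^2
//   4 N -> 0        rate N * <D_in> /(k_t Omega)
//   5 D -> 0        rate D * <N_in> /(k_t Omega)
//   6 N + D -> 0    rate N D /(k_c Omega)
//   7 N -> 0        rate N
//   8 D -> 0        rate D
//   9 R -> 0        rate R
// In the NSM the voxel volume V_i replaces Omega in the production and
// bimolecular scalings; signal-mediated degradations keep the whole-cell
// Omega (signals are per-cell quantities, not localized to voxels).

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

struct Pars {
  double bn, bd, br, kt, kc, krs, om;
  int m, s;
};

Pars unpack(const NumericVector& p) {
  Pars P;
  P.bn = p[0]; P.bd = p[1]; P.br = p[2];
  P.kt = p[3]; P.kc = p[4]; P.krs = p[5];
  P.m = (int)p[6]; P.s = (int)p[7]; P.om = p[8];
  return P;
}

inline double ipow(double x, int e) {
  if (e == 2) return x * x;
  if (e == 1) return x;
  return std::pow(x, (double)e);
}

// vol: volume used in production / bimolecular scalings (Omega, or V_i in
// the RDME); om: whole-cell volume used for signal scalings.
inline double propensities(const Pars& P, double vol,
                           double N, double D, double R,
                           double din, double dout, double nin,
                           const int* en, double* a) {
  const double r1 = 1.0 / (1.0 + ipow(R / vol, P.m));
  const double u = dout * N / (P.om * vol);
  const double us = ipow(u, P.s);
  const double r2 = (us > 0.0) ? us / (P.krs + us) : 0.0;
  a[0] = en[0] ? P.bn * vol : 0.0;
  a[1] = en[1] ? P.bd * vol * r1 : 0.0;
  a[2] = en[2] ? P.br * vol * r2 : 0.0;
  a[3] = en[3] ? N * din / (P.kt * P.om) : 0.0;
  a[4] = en[4] ? D * nin / (P.kt * P.om) : 0.0;
  a[5] = en[5] ? N * D / (P.kc * vol) : 0.0;
  a[6] = en[6] ? N : 0.0;
  a[7] = en[7] ? D : 0.0;
  a[8] = en[8] ? R : 0.0;
  double s = 0.0;
  for (int k = 0; k < 9; ++k) s += a[k];
  return s;
}

const int DN[9] = {+1, 0, 0, -1, 0, -1, -1, 0, 0};
const int DD[9] = {0, +1, 0, 0, -1, -1, 0, -1, 0};
const int DR[9] = {0, 0, +1, 0, 0, 0, 0, 0, -1};

// xoshiro256++ (public-domain algorithm), seeded through splitmix64;
// much faster than the standard-library engines in these event loops.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  inline double expdev() { return -std::log(unif_pos()); }
};

inline int pick(const double* a, int n, double total, Rng& rng) {
  double r = rng.unif() * total;
  double c = 0.0;
  for (int k = 0; k < n - 1; ++k) {
    c += a[k];
    if (r < c) return k;
  }
  return n - 1;
}

} // namespace

// Advance every cell (rows of `counts`) independently over [0, dt) by the
// direct method with frozen signals. counts: n x 3 (N, D, R); signals:
// n x 3 (d_in, d_out, n_in) in count units.
// [[Rcpp::export]]
IntegerMatrix ssa_chunk_cpp(IntegerMatrix counts, NumericMatrix signals,
                            NumericVector params, IntegerVector enable,
                            double dt, double seed) {
  const int nc = counts.nrow();
  const Pars P = unpack(params);
  int en[9];
  for (int k = 0; k < 9; ++k) en[k] = enable[k];
  Rng rng((uint64_t)seed);
  IntegerMatrix out(clone(counts));
  double a[9];
  for (int i = 0; i < nc; ++i) {
    double N = out(i, 0), D = out(i, 1), R = out(i, 2);
    const double din = signals(i, 0), dout = signals(i, 1), nin = signals(i, 2);
    const double c3 = din / (P.kt * P.om);   // per-N trans degradation
    const double c4 = nin / (P.kt * P.om);   // per-D trans degradation
    const double c5 = 1.0 / (P.kc * P.om);   // cis annihilation
    double t = 0.0;
    double a0 = propensities(P, P.om, N, D, R, din, dout, nin, en, a);
    long refresh = 0;
    for (;;) {
      if (!(a0 > 0.0)) break;
      if (!std::isfinite(a0)) stop("non-finite propensity");
      t += rng.expdev() / a0;
      if (t >= dt) break;
      // categorical draw; scan order puts the typically dominant reporter
      // channels first (statistically equivalent to the natural order)
      static const int ORD[9] = {2, 8, 1, 7, 0, 6, 3, 5, 4};
      int k;
      {
        double r = rng.unif() * a0, c = 0.0;
        k = ORD[8];
        for (int q = 0; q < 8; ++q) {
          c += a[ORD[q]];
          if (r < c) { k = ORD[q]; break; }
        }
      }
      N += DN[k]; D += DD[k]; R += DR[k];
      // incrementally refresh only the propensities the event touched
      double d = -a[2] - a[3] - a[5] - a[6] - a[4] - a[7] - a[1] - a[8];
      if (DN[k]) {
        const double u = dout * N / (P.om * P.om);
        const double us = ipow(u, P.s);
        a[2] = en[2] ? P.br * P.om * ((us > 0.0) ? us / (P.krs + us) : 0.0)
                     : 0.0;
        a[3] = en[3] ? N * c3 : 0.0;
        a[5] = en[5] ? N * D * c5 : 0.0;
        a[6] = en[6] ? N : 0.0;
      }
      if (DD[k]) {
        a[4] = en[4] ? D * c4 : 0.0;
        a[5] = en[5] ? N * D * c5 : 0.0;
        a[7] = en[7] ? D : 0.0;
      }
      if (DR[k]) {
        a[1] = en[1] ? P.bd * P.om / (1.0 + ipow(R / P.om, P.m)) : 0.0;
        a[8] = en[8] ? R : 0.0;
      }
      d += a[2] + a[3] + a[5] + a[6] + a[4] + a[7] + a[1] + a[8];
      a0 += d;
      // periodically rebuild a0 to cancel floating-point drift
      if (++refresh == 100000) {
        a0 = propensities(P, P.om, N, D, R, din, dout, nin, en, a);
        refresh = 0;
      }
    }
    out(i, 0) = (int)N; out(i, 1) = (int)D; out(i, 2) = (int)R;
  }
  return out;
}

// Single-cell direct-method trajectory with frozen signals, recorded at the
// sorted non-negative `times` (relative to the initial state at t = 0).
// [[Rcpp::export]]
IntegerMatrix ssa_traj_cpp(IntegerVector counts, NumericVector signals,
                           NumericVector params, IntegerVector enable,
                           NumericVector times, double seed) {
  const Pars P = unpack(params);
  int en[9];
  for (int k = 0; k < 9; ++k) en[k] = enable[k];
  Rng rng((uint64_t)seed);
  const int nt = times.size();
  IntegerMatrix out(nt, 3);
  double N = counts[0], D = counts[1], R = counts[2];
  const double din = signals[0], dout = signals[1], nin = signals[2];
  double t = 0.0, a[9];
  int j = 0;
  for (;;) {
    double a0 = propensities(P, P.om, N, D, R, din, dout, nin, en, a);
    double tnext;
    if (a0 > 0.0) {
      if (!std::isfinite(a0)) stop("non-finite propensity");
      tnext = t + rng.expdev() / a0;
    } else {
      tnext = std::numeric_limits<double>::infinity();
    }
    while (j < nt && times[j] < tnext) {
      out(j, 0) = (int)N; out(j, 1) = (int)D; out(j, 2) = (int)R;
      ++j;
    }
    if (j >= nt) break;
    t = tnext;
    int k = pick(a, 9, a0, rng);
    N += DN[k]; D += DD[k]; R += DR[k];
  }
  return out;
}

namespace {

// Indexed binary min-heap over (time, voxel index), ties broken by index.
struct Heap {
  std::vector<double> t;   // event time per voxel
  std::vector<int> heap;   // heap of voxel indices
  std::vector<int> pos;    // voxel -> heap slot
  explicit Heap(int n) : t(n), heap(n), pos(n) {
    for (int i = 0; i < n; ++i) { heap[i] = i; pos[i] = i; }
  }
  bool less(int a, int b) const {
    return (t[a] < t[b]) || (t[a] == t[b] && a < b);
  }
  void swap_slots(int i, int j) {
    std::swap(heap[i], heap[j]);
    pos[heap[i]] = i; pos[heap[j]] = j;
  }
  void up(int i) {
    while (i > 0) {
      int p = (i - 1) / 2;
      if (less(heap[i], heap[p])) { swap_slots(i, p); i = p; } else break;
    }
  }
  void down(int i) {
    int n = (int)heap.size();
    for (;;) {
      int l = 2 * i + 1, r = l + 1, m = i;
      if (l < n && less(heap[l], heap[m])) m = l;
      if (r < n && less(heap[r], heap[m])) m = r;
      if (m == i) break;
      swap_slots(i, m); i = m;
    }
  }
  void update(int v, double tv) {
    t[v] = tv;
    up(pos[v]); down(pos[v]);
  }
  int top() const { return heap[0]; }
};

} // namespace

// Next Subvolume Method over one cell's mesh with frozen per-cell signals.
// state: nv x 3 counts; vol: voxel volumes (sum = Omega); CSR adjacency
// (eptr 0-based length nv+1, enbr neighbor ids, erate per-molecule jump
// rate i -> nbr, identical for all species); dt: horizon.
// [[Rcpp::export]]
IntegerMatrix nsm_cpp(IntegerMatrix state, NumericVector vol,
                      IntegerVector eptr, IntegerVector enbr,
                      NumericVector erate,
                      NumericVector params, IntegerVector enable,
                      NumericVector signals, double dt, double seed) {
  const int nv = state.nrow();
  const Pars P = unpack(params);
  int en[9];
  for (int k = 0; k < 9; ++k) en[k] = enable[k];
  const double din = signals[0], dout = signals[1], nin = signals[2];
  Rng rng((uint64_t)seed);
  IntegerMatrix st(clone(state));

  std::vector<double> jtot(nv), ar(nv), ad(nv);
  for (int i = 0; i < nv; ++i) {
    double s = 0.0;
    for (int e = eptr[i]; e < eptr[i + 1]; ++e) s += erate[e];
    jtot[i] = s;
  }
  double a[9];
  auto recompute = [&](int i) {
    ar[i] = propensities(P, vol[i], st(i, 0), st(i, 1), st(i, 2),
                         din, dout, nin, en, a);
    ad[i] = (st(i, 0) + st(i, 1) + st(i, 2)) * jtot[i];
    if (!std::isfinite(ar[i] + ad[i])) stop("non-finite propensity");
  };

  Heap H(nv);
  for (int i = 0; i < nv; ++i) {
    recompute(i);
    double tot = ar[i] + ad[i];
    H.t[i] = (tot > 0.0) ? rng.expdev() / tot
                         : std::numeric_limits<double>::infinity();
  }
  for (int i = nv / 2; i >= 0; --i) H.down(i);

  for (;;) {
    int v = H.top();
    double tnow = H.t[v];
    if (!(tnow < dt)) break;
    double tot = ar[v] + ad[v];
    if (rng.unif() * tot < ad[v]) {
      // diffusion event: species proportional to counts, then destination
      double cs[3] = {(double)st(v, 0), (double)st(v, 1), (double)st(v, 2)};
      double csum = cs[0] + cs[1] + cs[2];
      int sp = pick(cs, 3, csum, rng);
      // destination among edges, proportional to erate
      int e0 = eptr[v], ne = eptr[v + 1] - e0;
      double r = rng.unif() * jtot[v], c = 0.0;
      int ei = ne - 1;
      for (int e = 0; e < ne - 1; ++e) {
        c += erate[e0 + e];
        if (r < c) { ei = e; break; }
      }
      int w = enbr[e0 + ei];
      st(v, sp) -= 1;
      st(w, sp) += 1;
      double oldw = ar[w] + ad[w];
      recompute(v);
      recompute(w);
      double newv = ar[v] + ad[v], neww = ar[w] + ad[w];
      H.update(v, newv > 0.0 ? tnow + rng.expdev() / newv
                             : std::numeric_limits<double>::infinity());
      double tw;
      if (neww <= 0.0) tw = std::numeric_limits<double>::infinity();
      else if (oldw > 0.0 && std::isfinite(H.t[w]))
        tw = tnow + (oldw / neww) * (H.t[w] - tnow);
      else tw = tnow + rng.expdev() / neww;
      H.update(w, tw);
    } else {
      // reaction event in voxel v
      propensities(P, vol[v], st(v, 0), st(v, 1), st(v, 2),
                   din, dout, nin, en, a);
      int k = pick(a, 9, ar[v], rng);
      st(v, 0) += DN[k]; st(v, 1) += DD[k]; st(v, 2) += DR[k];
      recompute(v);
      double newv = ar[v] + ad[v];
      H.update(v, newv > 0.0 ? tnow + rng.expdev() / newv
                             : std::numeric_limits<double>::infinity());
    }
  }
  return st;
}
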