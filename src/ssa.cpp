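// Exact stochastic simulation (Gillespie direct method) and fused
// proposal evaluators for the ABC drivers.  All simulation randomness
// comes from a self-contained xoshiro256** generator so that a scalar
// seed plus a vector of substream indices reproduces any trajectory
// bit-for-bit, independently of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 finalizer used for seeding / substream derivation,
// xoshiro256** for the event loop.

static inline uint64_t sm_mix(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  void seed(uint64_t x) {
    uint64_t st = x;
    for (int i = 0; i < 4; ++i) { st = sm_mix(st); s[i] = st; }
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x9E3779B97F4A7C15ULL;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Chain a base seed through a vector of (1-based) substream indices.
// The result is truncated to 53 bits so it survives a round trip
// through an R double unchanged.
static uint64_t derive64(uint64_t base, const int *ids, int nid) {
  uint64_t x = base;
  for (int i = 0; i < nid; ++i) {
    x = sm_mix(x ^ ((uint64_t)(uint32_t)ids[i] * 0xD1B54A32D192ED03ULL));
  }
  return x >> 11;
}

// [[Rcpp::export]]
double cpp_derive_seed(double seed, IntegerVector ids) {
  uint64_t out = derive64((uint64_t)seed, ids.begin(), ids.size());
  return (double)out;
}

// ---------------------------------------------------------------------------
// Compiled reaction network.

enum RType { R_ZERO = 0, R_UNI = 1, R_BI = 2, R_DIMER = 3 };

#define ABCSLD_MAX_R 32  // compiled reaction limit (benchmarks use 4 and 8)

struct Net {
  int m, S;                       // reactions, species
  int type[ABCSLD_MAX_R], i1[ABCSLD_MAX_R], i2[ABCSLD_MAX_R];
  double c[ABCSLD_MAX_R];         // stochastic rate constants
  double dimer_fac;               // 0.5 combinatorial, 1.0 "full" convention
  std::vector<int> delta;         // state-change vectors, flat, stride S

  void compile(const IntegerMatrix &R, const IntegerMatrix &P,
               const NumericVector &rates, bool dfull) {
    m = R.nrow(); S = R.ncol();
    if (m > ABCSLD_MAX_R) stop("too many reactions (limit %d)", ABCSLD_MAX_R);
    dimer_fac = dfull ? 1.0 : 0.5;
    delta.assign((size_t)m * S, 0);
    for (int j = 0; j < m; ++j) {
      int nsp = 0, a = -1, b = -1, tot = 0;
      for (int s = 0; s < S; ++s) {
        int r = R(j, s);
        delta[(size_t)j * S + s] = P(j, s) - r;
        if (r > 0) { if (nsp == 0) a = s; else b = s; ++nsp; tot += r; }
      }
      if (tot == 0)            { type[j] = R_ZERO; i1[j] = i2[j] = 0; }
      else if (tot == 1)       { type[j] = R_UNI;   i1[j] = i2[j] = a; }
      else if (nsp == 1)       { type[j] = R_DIMER; i1[j] = i2[j] = a; }
      else                     { type[j] = R_BI;    i1[j] = a; i2[j] = b; }
      if (tot > 2) stop("reactant molecularity above 2 is not supported");
      c[j] = rates[j];
      if (!R_FINITE(c[j]) || c[j] < 0) stop("invalid rate constant");
    }
  }
};

// One exact realization over a time interval of given duration.
// The waiting-time draw that overshoots the interval end is discarded,
// so restarting at recording boundaries is statistically exact and
// grid simulation is bit-identical to chained interval simulation.
static void run_interval(const Net &net, double *x, double duration,
                         Rng &g, double max_events, double *events) {
  double t = 0.0, ev = 0.0;
  double a[ABCSLD_MAX_R];
  const int m = net.m, S = net.S;
  const int *type = net.type, *i1 = net.i1, *i2 = net.i2;
  const double *c = net.c;
  const int *delta = net.delta.data();
  const double dfac = net.dimer_fac;
  for (;;) {
    double a0 = 0.0;
    for (int j = 0; j < m; ++j) {
      double aj;
      switch (type[j]) {
      case R_ZERO:  aj = c[j]; break;
      case R_UNI:   aj = c[j] * x[i1[j]]; break;
      case R_BI:    aj = c[j] * x[i1[j]] * x[i2[j]]; break;
      default: { double n = x[i1[j]]; aj = dfac * c[j] * n * (n - 1.0); }
      }
      a[j] = aj; a0 += aj;
    }
    if (a0 <= 0.0) break;  // frozen: state persists to end of interval
    if (!(a0 < 1e300)) { *events += ev; stop("propensity overflow"); }
    t += -std::log(1.0 - g.unif()) / a0;
    if (t > duration) break;
    double u = g.unif() * a0, cum = 0.0;
    int j = m - 1;
    for (int jj = 0; jj < m; ++jj) {
      cum += a[jj];
      if (u <= cum) { j = jj; break; }
    }
    const int *d = delta + (size_t)j * S;
    for (int s = 0; s < S; ++s) x[s] += d[s];
    if (++ev > max_events - *events) {
      *events += ev;
      stop("event-count guard exceeded (max_events = %g)", max_events);
    }
  }
  *events += ev;
}

// ---------------------------------------------------------------------------
// Exported simulators.

// [[Rcpp::export]]
NumericVector cpp_ssa_interval(IntegerMatrix reactants, IntegerMatrix products,
                               NumericVector rates, NumericVector state,
                               double duration, double seed,
                               double max_events, bool dimer_full) {
  Net net; net.compile(reactants, products, rates, dimer_full);
  std::vector<double> x(state.begin(), state.end());
  Rng g; g.seed((uint64_t)seed);
  double ev = 0.0;
  run_interval(net, x.data(), duration, g, max_events, &ev);
  return NumericVector(x.begin(), x.end());
}

// Record on an increasing grid; one substream per interval, derived from
// the scalar seed with index l (1-based grid position).
// [[Rcpp::export]]
NumericMatrix cpp_ssa_grid(IntegerMatrix reactants, IntegerMatrix products,
                           NumericVector rates, NumericVector state,
                           double t_start, NumericVector times,
                           double seed, double max_events, bool dimer_full) {
  Net net; net.compile(reactants, products, rates, dimer_full);
  int n = times.size();
  NumericMatrix out(n, net.S);
  std::vector<double> x(state.begin(), state.end());
  double prev = t_start, ev = 0.0;
  for (int l = 0; l < n; ++l) {
    int id = l + 1;
    Rng g; g.seed(derive64((uint64_t)seed, &id, 1));
    run_interval(net, x.data(), times[l] - prev, g, max_events, &ev);
    for (int s = 0; s < net.S; ++s) out(l, s) = x[s];
    prev = times[l];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Point test of the discrepancy tolerance alpha: every species must
// satisfy |X - Y| <= alpha*X (X > 0) or |Y| <= zero_floor (X == 0).
static inline bool point_pass(const double *X, const double *Y, int S,
                              double alpha, double zero_floor) {
  for (int s = 0; s < S; ++s) {
    if (X[s] > 0.0) {
      if (std::fabs(X[s] - Y[s]) > alpha * X[s]) return false;
    } else {
      if (std::fabs(Y[s]) > zero_floor) return false;
    }
  }
  return true;
}

// Fused evaluator for the per-interval (transitional-density) error:
// for l = 1..n restart B replicates from the OBSERVED state X_{l-1},
// simulate one step dt, and count failures of the alpha point test.
// Rejects early once the failure total exceeds max_fail.
// obs is the (n+1) x S matrix of observed states including row 1 = X_0.
// [[Rcpp::export]]
List cpp_eval_sld1(IntegerMatrix reactants, IntegerMatrix products,
                   NumericVector theta, NumericMatrix obs, double dt,
                   int B, double alpha, double zero_floor, double max_fail,
                   double seed, double max_events, bool dimer_full) {
  Net net; net.compile(reactants, products, theta, dimer_full);
  int n = obs.nrow() - 1, S = obs.ncol();
  IntegerVector b(n);
  double total = 0.0, ev = 0.0;
  std::vector<double> x(S), X(S);
  bool accept = true;
  for (int l = 1; l <= n && accept; ++l) {
    for (int s = 0; s < S; ++s) X[s] = obs(l, s);
    for (int m = 1; m <= B; ++m) {
      int ids[2] = { l, m };
      Rng g; g.seed(derive64((uint64_t)seed, ids, 2));
      for (int s = 0; s < S; ++s) x[s] = obs(l - 1, s);
      run_interval(net, x.data(), dt, g, max_events, &ev);
      if (!point_pass(X.data(), x.data(), S, alpha, zero_floor)) {
        ++b[l - 1]; total += 1.0;
        if (total > max_fail) { accept = false; break; }
      }
    }
  }
  return List::create(_["accept"] = accept, _["b"] = b,
                      _["total_fail"] = total, _["events"] = ev);
}

// Fused evaluator for the whole-trajectory per-time-point error: each of
// the B replicates is one trajectory from X_0 over the full grid; failures
// of the alpha point test are accumulated over (m, l).  Replicate m uses
// substream derive(seed, m) and within it one substream per interval, so
// a replicate reproduces cpp_ssa_grid run with that derived seed.
// [[Rcpp::export]]
List cpp_eval_sld2(IntegerMatrix reactants, IntegerMatrix products,
                   NumericVector theta, NumericMatrix obs, double dt,
                   int B, double alpha, double zero_floor, double max_fail,
                   double seed, double max_events, bool dimer_full) {
  Net net; net.compile(reactants, products, theta, dimer_full);
  int n = obs.nrow() - 1, S = obs.ncol();
  IntegerVector b(n);
  double total = 0.0, ev = 0.0;
  std::vector<double> x(S), X(S);
  bool accept = true;
  for (int m = 1; m <= B && accept; ++m) {
    uint64_t mseed = derive64((uint64_t)seed, &m, 1);
    for (int s = 0; s < S; ++s) x[s] = obs(0, s);
    for (int l = 1; l <= n; ++l) {
      Rng g; g.seed(derive64(mseed, &l, 1));
      run_interval(net, x.data(), dt, g, max_events, &ev);
      for (int s = 0; s < S; ++s) X[s] = obs(l, s);
      if (!point_pass(X.data(), x.data(), S, alpha, zero_floor)) {
        ++b[l - 1]; total += 1.0;
        if (total > max_fail) { accept = false; break; }
      }
    }
  }
  return List::create(_["accept"] = accept, _["b"] = b,
                      _["total_fail"] = total, _["events"] = ev);
}

// Generic ABC SMC evaluator: B whole-trajectory replicates, each reduced
// to one scalar distance; b_k counts replicates with distance <= epsilon.
// dist codes: 0 rms_relative, 1 rms_absolute, 2 match_fraction.
// [[Rcpp::export]]
List cpp_eval_smc(IntegerMatrix reactants, IntegerMatrix products,
                  NumericVector theta, NumericMatrix obs, double dt,
                  int B, double epsilon, int dist, double alpha,
                  double zero_floor, double seed, double max_events,
                  bool dimer_full) {
  Net net; net.compile(reactants, products, theta, dimer_full);
  int n = obs.nrow() - 1, S = obs.ncol();
  double ev = 0.0;
  int bk = 0;
  std::vector<double> x(S), X(S);
  for (int m = 1; m <= B; ++m) {
    uint64_t mseed = derive64((uint64_t)seed, &m, 1);
    for (int s = 0; s < S; ++s) x[s] = obs(0, s);
    double ss = 0.0, nfail = 0.0;
    for (int l = 1; l <= n; ++l) {
      Rng g; g.seed(derive64(mseed, &l, 1));
      run_interval(net, x.data(), dt, g, max_events, &ev);
      for (int s = 0; s < S; ++s) {
        X[s] = obs(l, s);
        double diff = X[s] - x[s];
        if (dist == 0) { double den = X[s] > 1.0 ? X[s] : 1.0; diff /= den; }
        ss += diff * diff;
      }
      if (dist == 2 && !point_pass(X.data(), x.data(), S, alpha, zero_floor))
        nfail += 1.0;
    }
    double d = (dist == 2) ? nfail / n : std::sqrt(ss / (n * S));
    if (d <= epsilon) ++bk;
  }
  return List::create(_["accept"] = bk > 0, _["bk"] = bk, _["events"] = ev);
}
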