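// BAOAB Langevin integrator on EVB mapping potentials for the surrogate
// solute + bath systems. The solute is one coordinate x with two harmonic
// diabats mixed at mapping parameter lambda; n_bath harmonic modes share an
// x-dependent stiffness k(x). Samples (x, eps1, eps2, E_g, eps_lambda) are
// recorded every `stride` steps; all randomness comes from a counter-hashed
// 64-bit stream so any single window is independently reproducible.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double KB = 1.9872041e-3; // kcal/mol/K

// splitmix64: tiny, well-mixed 64-bit generator; adequate for thermostat
// noise and fully deterministic across platforms.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { // (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double gauss() { // Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586476925287 * v;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// Documented seed-derivation scheme: a fixed splitmix64 hash of
// (master_seed, replicate, temperature in mK, window, phase).
static uint64_t hash_seed(uint64_t h, uint64_t v) {
  h ^= v + 0x9e3779b97f4a7c15ULL + (h << 6) + (h >> 2);
  Rng r(h);
  return r.next_u64();
}

// [[Rcpp::export(name = ".derive_stream_seed")]]
NumericVector derive_stream_seed(int master_seed, int replicate_id,
                                 double temperature, int window, int phase) {
  uint64_t h = 0x6a09e667f3bcc908ULL;
  h = hash_seed(h, (uint64_t)(int64_t)master_seed);
  h = hash_seed(h, (uint64_t)(int64_t)replicate_id);
  h = hash_seed(h, (uint64_t)(int64_t)llround(temperature * 1000.0));
  h = hash_seed(h, (uint64_t)(int64_t)window);
  h = hash_seed(h, (uint64_t)(int64_t)phase);
  // return as two doubles exactly representing 32-bit halves
  return NumericVector::create((double)(uint32_t)(h >> 32),
                               (double)(uint32_t)h);
}

struct Sys {
  double k1, x1, a1, k2, x2, a2, h12;
  int n_bath;
  double lnk_ref;
  std::vector<double> d, c, w;
  std::vector<double> inv_m; // length 1 + n_bath

  void bath_k(double x, double &k, double &dlnk) const {
    double lnk = lnk_ref, dd = 0.0;
    for (size_t j = 0; j < d.size(); ++j) {
      double u = (x - c[j]) / w[j];
      double t = std::tanh(u);
      lnk += d[j] * 0.5 * (1.0 + t);
      dd += d[j] * 0.5 * (1.0 - t * t) / w[j];
    }
    k = std::exp(lnk);
    dlnk = dd;
  }
};

static Sys unpack(const List &sys) {
  Sys s;
  s.k1 = sys["k1"]; s.x1 = sys["x1"]; s.a1 = sys["a1"];
  s.k2 = sys["k2"]; s.x2 = sys["x2"]; s.a2 = sys["a2"];
  s.h12 = sys["h12"]; s.n_bath = sys["n_bath"];
  s.lnk_ref = std::log((double)sys["k_bath_ref"]);
  s.d = as<std::vector<double>>(sys["bath_delta"]);
  s.c = as<std::vector<double>>(sys["bath_center"]);
  s.w = as<std::vector<double>>(sys["bath_width"]);
  std::vector<double> m = as<std::vector<double>>(sys["masses"]);
  s.inv_m.resize(m.size());
  for (size_t i = 0; i < m.size(); ++i) s.inv_m[i] = 1.0 / m[i];
  return s;
}

// Forces on (x, y_1..y_nb) under the mapping potential + harmonic restraint.
static void forces(const Sys &s, double lam, const std::vector<double> &q,
                   double restraint_k, double restraint_x0,
                   std::vector<double> &f) {
  double x = q[0];
  double g1 = s.k1 * (x - s.x1), g2 = s.k2 * (x - s.x2);
  double fx = -((1.0 - lam) * g1 + lam * g2);
  if (s.n_bath > 0) {
    double k, dlnk;
    s.bath_k(x, k, dlnk);
    double sumy2 = 0.0;
    for (int i = 1; i <= s.n_bath; ++i) sumy2 += q[i] * q[i];
    fx -= 0.5 * k * dlnk * sumy2;
    for (int i = 1; i <= s.n_bath; ++i) f[i] = -k * q[i];
  }
  if (restraint_k > 0) fx -= restraint_k * (x - restraint_x0);
  f[0] = fx;
}

// [[Rcpp::export(name = ".langevin_kernel")]]
List langevin_kernel(List sys, double lam, double temperature, int n_steps,
                     double dt, double friction, NumericVector state,
                     double restraint_k, double restraint_x0,
                     int stride, bool record,
                     int master_seed, int replicate_id, int window, int phase) {
  Sys s = unpack(sys);
  int nd = 1 + s.n_bath;
  if (state.size() != 2 * nd) stop("state must have length 2*(1 + n_bath)");
  std::vector<double> q(nd), v(nd), f(nd, 0.0);
  for (int i = 0; i < nd; ++i) { q[i] = state[i]; v[i] = state[nd + i]; }

  uint64_t h = 0x6a09e667f3bcc908ULL;
  h = hash_seed(h, (uint64_t)(int64_t)master_seed);
  h = hash_seed(h, (uint64_t)(int64_t)replicate_id);
  h = hash_seed(h, (uint64_t)(int64_t)llround(temperature * 1000.0));
  h = hash_seed(h, (uint64_t)(int64_t)window);
  h = hash_seed(h, (uint64_t)(int64_t)phase);
  Rng rng(h);

  double kT = KB * temperature;
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  int n_rec = record ? (n_steps / stride) : 0;
  NumericMatrix samples(n_rec, 5);

  forces(s, lam, q, restraint_k, restraint_x0, f);
  int irec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < nd; ++i) v[i] += 0.5 * dt * f[i] * s.inv_m[i]; // B
    for (int i = 0; i < nd; ++i) q[i] += 0.5 * dt * v[i];              // A
    for (int i = 0; i < nd; ++i) {                                     // O
      double sd = std::sqrt(kT * s.inv_m[i]);
      v[i] = c1 * v[i] + c2 * sd * rng.gauss();
    }
    for (int i = 0; i < nd; ++i) q[i] += 0.5 * dt * v[i];              // A
    forces(s, lam, q, restraint_k, restraint_x0, f);
    for (int i = 0; i < nd; ++i) v[i] += 0.5 * dt * f[i] * s.inv_m[i]; // B

    if (!std::isfinite(q[0]) || std::fabs(q[0]) > 1e6) {
      stop("divergent trajectory at window %d, step %d (x = %g)",
           window, step, q[0]);
    }
    if (record && step % stride == 0) {
      double x = q[0];
      double e1 = 0.5 * s.k1 * (x - s.x1) * (x - s.x1) + s.a1;
      double e2 = 0.5 * s.k2 * (x - s.x2) * (x - s.x2) + s.a2;
      double dlt = e1 - e2;
      double eg = 0.5 * (e1 + e2) - 0.5 * std::sqrt(dlt * dlt + 4.0 * s.h12 * s.h12);
      samples(irec, 0) = x;
      samples(irec, 1) = e1;
      samples(irec, 2) = e2;
      samples(irec, 3) = eg;
      samples(irec, 4) = (1.0 - lam) * e1 + lam * e2;
      ++irec;
    }
  }
  NumericVector out_state(2 * nd);
  for (int i = 0; i < nd; ++i) { out_state[i] = q[i]; out_state[nd + i] = v[i]; }
  return List::create(_["state"] = out_state, _["samples"] = samples);
}

// Maxwell-Boltzmann velocity draw with the same deterministic stream.
// [[Rcpp::export(name = ".maxwell_kernel")]]
NumericVector maxwell_kernel(NumericVector masses, double temperature,
                             int master_seed, int replicate_id, int window,
                             int phase) {
  uint64_t h = 0x6a09e667f3bcc908ULL;
  h = hash_seed(h, (uint64_t)(int64_t)master_seed);
  h = hash_seed(h, (uint64_t)(int64_t)replicate_id);
  h = hash_seed(h, (uint64_t)(int64_t)llround(temperature * 1000.0));
  h = hash_seed(h, (uint64_t)(int64_t)window);
  h = hash_seed(h, (uint64_t)(int64_t)phase);
  Rng rng(h);
  int n = masses.size();
  NumericVector v(n);
  double kT = KB * temperature;
  for (int i = 0; i < n; ++i) v[i] = std::sqrt(kT / masses[i]) * rng.gauss();
  return v;
}
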