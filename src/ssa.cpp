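#include <Rcpp.h>
using namespace Rcpp;

// Exact (Gillespie direct-method) simulation cores.  All three use R's RNG,
// so set.seed() in R makes paths bit-identical.  Trajectories are returned
// as the change-points of one tracked species (piecewise-constant paths);
// statistics in R weight each value by its dwell time.

static inline double rexp_unit() {
  // -log(U) with U in (0,1); unif_rand never returns exactly 0 or 1
  return -std::log(unif_rand());
}

// Full CCC with explicit complexes: species
// 0:m0 1:m1 2:m2 3:c 4:cstar 5:cm0 6:cstarm1 and 9 elementary reactions.
// track = 7 records the total intermediate m1 + c*m1 (the reduced models'
// [m1] variable); track = 8 records the total first metabolite m0 + cm0.
// [[Rcpp::export]]
List ssa_full_cpp(NumericVector pars, IntegerVector x0, double t_end,
                  int track, double max_events) {
  const double kin = pars["kin"], kleak = pars["kleak"], kout = pars["kout"],
               kc = pars["kc"], kp = pars["kp"],
               ka0 = pars["ka0"], kd0 = pars["kd0"],
               ka1 = pars["ka1"], kd1 = pars["kd1"];
  std::vector<long long> x(7);
  for (int i = 0; i < 7; ++i) x[i] = x0[i];
  const long long carrier0 = x[3] + x[4] + x[5] + x[6];

  std::vector<double> times; times.reserve(1 << 16);
  std::vector<double> vals;  vals.reserve(1 << 16);
  auto tracked = [&]() -> long long {
    if (track == 7) return x[1] + x[6];
    if (track == 8) return x[0] + x[5];
    return x[track];
  };
  double t = 0.0;
  times.push_back(0.0); vals.push_back((double)tracked());
  double n_events = 0.0;
  bool carrier_ok = true, overflow = false;
  double a[9];

  while (t < t_end && n_events < max_events) {
    a[0] = kin;
    a[1] = kleak * x[0];
    a[2] = ka0 * (double)x[3] * (double)x[0];
    a[3] = kd0 * x[5];
    a[4] = kc * x[5];
    a[5] = ka1 * (double)x[4] * (double)x[1];
    a[6] = kd1 * x[6];
    a[7] = kp * x[6];
    a[8] = kout * x[2];
    double a0 = 0.0;
    for (int i = 0; i < 9; ++i) a0 += a[i];
    if (a0 <= 0.0) { t = t_end; break; }
    if (!R_finite(a0) || a0 > 1e15) { overflow = true; break; }
    t += rexp_unit() / a0;
    if (t >= t_end) { t = t_end; break; }
    double r = unif_rand() * a0, cum = 0.0;
    int j = 8;
    for (int i = 0; i < 9; ++i) { cum += a[i]; if (r <= cum) { j = i; break; } }
    long long before = tracked();
    switch (j) {
      case 0: x[0] += 1; break;                       // influx
      case 1: x[0] -= 1; break;                       // leak
      case 2: x[3] -= 1; x[0] -= 1; x[5] += 1; break; // c + m0 -> cm0
      case 3: x[5] -= 1; x[3] += 1; x[0] += 1; break; // cm0 -> c + m0
      case 4: x[5] -= 1; x[1] += 1; x[4] += 1; break; // cm0 -> m1 + c*
      case 5: x[4] -= 1; x[1] -= 1; x[6] += 1; break; // c* + m1 -> c*m1
      case 6: x[6] -= 1; x[4] += 1; x[1] += 1; break; // c*m1 -> c* + m1
      case 7: x[6] -= 1; x[2] += 1; x[3] += 1; break; // c*m1 -> m2 + c
      case 8: x[2] -= 1; break;                       // efflux
    }
    n_events += 1.0;
    if (x[3] + x[4] + x[5] + x[6] != carrier0) carrier_ok = false;
    if (tracked() != before) {
      times.push_back(t);
      vals.push_back((double)tracked());
    }
  }
  IntegerVector xf(7);
  for (int i = 0; i < 7; ++i) xf[i] = (int)std::min<long long>(x[i], INT_MAX);
  return List::create(_["time"] = wrap(times), _["n"] = wrap(vals),
                      _["t_final"] = t, _["n_events"] = n_events,
                      _["final_state"] = xf,
                      _["carrier_conserved"] = carrier_ok,
                      _["overflow"] = overflow);
}

// Perfect-binding (K -> 0) limit: birth-death chain for n = m1 count.
// saturated: birth kc*(cmax - n), death kp*n  (carrier-feedback process)
// otherwise: birth kin (constant),  death kp*n  (Poissonian)
// [[Rcpp::export]]
List ssa_limit_cpp(double kc, double kp, int cmax, double kin, bool saturated,
                   int n0, double t_end, double max_events) {
  long long n = n0;
  std::vector<double> times; times.reserve(1 << 16);
  std::vector<double> vals;  vals.reserve(1 << 16);
  double t = 0.0, n_events = 0.0;
  times.push_back(0.0); vals.push_back((double)n);
  while (t < t_end && n_events < max_events) {
    double b = saturated ? kc * (double)(cmax - n) : kin;
    double d = kp * (double)n;
    double a0 = b + d;
    if (a0 <= 0.0) { t = t_end; break; }
    t += rexp_unit() / a0;
    if (t >= t_end) { t = t_end; break; }
    if (unif_rand() * a0 <= b) n += 1; else n -= 1;
    n_events += 1.0;
    times.push_back(t);
    vals.push_back((double)n);
  }
  return List::create(_["time"] = wrap(times), _["n"] = wrap(vals),
                      _["t_final"] = t, _["n_events"] = n_events);
}

// Double Michaelis-Menten comparator: two independent saturated pools, no
// shared conservation.  Birth kc*c1 (constant), death kp*c2 for n > 0 —
// an unbiased random walk when kc*c1 = kp*c2; the Fano factor never drops
// below 1.
// [[Rcpp::export]]
List ssa_double_mm_cpp(double kc, double kp, double c1, double c2,
                       int n0, double t_end, double max_events,
                       double n_cap) {
  double n = n0;
  std::vector<double> times; times.reserve(1 << 12);
  std::vector<double> vals;  vals.reserve(1 << 12);
  double t = 0.0, n_events = 0.0;
  bool truncated = false;
  times.push_back(0.0); vals.push_back(n);
  const double b = kc * c1;
  while (t < t_end && n_events < max_events) {
    double d = (n > 0) ? kp * c2 : 0.0;
    double a0 = b + d;
    if (a0 <= 0.0) { t = t_end; break; }
    t += rexp_unit() / a0;
    if (t >= t_end) { t = t_end; break; }
    if (unif_rand() * a0 <= b) n += 1; else n -= 1;
    n_events += 1.0;
    times.push_back(t);
    vals.push_back(n);
    if (n > n_cap) { truncated = true; break; }
  }
  return List::create(_["time"] = wrap(times), _["n"] = wrap(vals),
                      _["t_final"] = t, _["n_events"] = n_events,
                      _["truncated"] = truncated);
}

// General tabulated birth-death chain on 0..nmax (cross-checks the
// master-equation stationary law).
// [[Rcpp::export]]
List ssa_bd_cpp(NumericVector birth, NumericVector death, int n0,
                double t_end, double max_events) {
  const int nmax = birth.size() - 1;
  if (death.size() != birth.size()) stop("birth and death lengths differ");
  int n = n0;
  std::vector<double> times; times.reserve(1 << 16);
  std::vector<double> vals;  vals.reserve(1 << 16);
  double t = 0.0, n_events = 0.0;
  times.push_back(0.0); vals.push_back((double)n);
  while (t < t_end && n_events < max_events) {
    double b = (n < nmax) ? birth[n] : 0.0;
    double d = (n > 0) ? death[n] : 0.0;
    double a0 = b + d;
    if (a0 <= 0.0) { t = t_end; break; }
    t += rexp_unit() / a0;
    if (t >= t_end) { t = t_end; break; }
    if (unif_rand() * a0 <= b) n += 1; else n -= 1;
    n_events += 1.0;
    times.push_back(t);
    vals.push_back((double)n);
  }
  return List::create(_["time"] = wrap(times), _["n"] = wrap(vals),
                      _["t_final"] = t, _["n_events"] = n_events);
}
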