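#include <Rcpp.h>
using namespace Rcpp;

// Propensities of the two-component positive-feedback switch.
// Channels: 0 basal x-production (k1), 1 Hill x-production by y,
//           2 x-degradation, 3 Hill y-production by x, 4 y-degradation.
// The rate laws equal the deterministic ones; the network is not
// elementary, so rate laws stand in for mass-action propensities.
static inline void propensities(double x, double y, const double* p,
                                double* a) {
  // p = {k1, V1, V2, M1, M2, h, u1, u2}
  const double h = p[5];
  const double yh = std::pow(y, h), xh = std::pow(x, h);
  a[0] = p[0];
  a[1] = p[1] * yh / (std::pow(p[3], h) + yh);
  a[2] = p[6] * x;
  a[3] = p[2] * xh / (std::pow(p[4], h) + xh);
  a[4] = p[7] * y;
}

static inline int pick_channel(const double* a, double a0) {
  double r = unif_rand() * a0, c = 0.0;
  for (int k = 0; k < 4; ++k) {
    c += a[k];
    if (r <= c) return k;
  }
  return 4;
}

static inline void apply(int ch, int& x, int& y) {
  if (ch == 0 || ch == 1) ++x;
  else if (ch == 2) --x;
  else if (ch == 3) ++y;
  else --y;
}

// Direct-method Gillespie run storing the full event sequence.
// mode: 0 free, 1 absorbing once x + y > B, 2 reflecting at x + y = B
// (production events that would leave the region have zero propensity).
// [[Rcpp::export(name = ".ssaRun")]]
List ssa_run(NumericVector par, int x0, int y0, double t_max,
             int mode, int B, double max_events) {
  std::vector<double> tv;
  std::vector<int> xv, yv;
  tv.reserve(1024); xv.reserve(1024); yv.reserve(1024);
  double t = 0.0, a[5];
  int x = x0, y = y0;
  bool absorbed = false;
  double t_abs = NA_REAL;
  tv.push_back(t); xv.push_back(x); yv.push_back(y);
  for (double ev = 0; ev < max_events; ++ev) {
    propensities(x, y, REAL(par), a);
    if (mode == 2 && x + y >= B) a[0] = a[1] = a[3] = 0.0;
    const double a0 = a[0] + a[1] + a[2] + a[3] + a[4];
    if (a0 <= 0.0) stop("zero total propensity at (%d, %d)", x, y);
    const double dt = -std::log(unif_rand()) / a0;
    if (t + dt > t_max) break;
    t += dt;
    apply(pick_channel(a, a0), x, y);
    tv.push_back(t); xv.push_back(x); yv.push_back(y);
    if (mode == 1 && x + y > B) { absorbed = true; t_abs = t; break; }
  }
  return List::create(_["time"] = tv, _["x"] = xv, _["y"] = yv,
                      _["absorbed"] = absorbed, _["t_abs"] = t_abs);
}

// Time-weighted occupancy of (x, y) for a free-running realization,
// accumulated on the fly so long runs need no event storage.  States with
// a coordinate above `cap` are recorded in the edge bin (dynamics are
// unaffected).
// [[Rcpp::export(name = ".ssaOccupancy")]]
NumericMatrix ssa_occupancy(NumericVector par, int x0, int y0,
                            double t_max, double burn_in, int cap) {
  if (burn_in >= t_max) stop("burn-in must be shorter than the run");
  NumericMatrix occ(cap + 1, cap + 1);  // [x, y], minutes of occupancy
  double t = 0.0, a[5];
  int x = x0, y = y0;
  while (t < t_max) {
    propensities(x, y, REAL(par), a);
    const double a0 = a[0] + a[1] + a[2] + a[3] + a[4];
    if (a0 <= 0.0) stop("zero total propensity at (%d, %d)", x, y);
    const double dt = -std::log(unif_rand()) / a0;
    const double t1 = std::min(t + dt, t_max);
    if (t1 > burn_in)
      occ(std::min(x, cap), std::min(y, cap)) += t1 - std::max(t, burn_in);
    t += dt;
    if (t >= t_max) break;
    apply(pick_channel(a, a0), x, y);
  }
  return occ;
}

// First-passage time to the absorbing macrostate (x + y > B), in minutes;
// NA if not reached before t_max.
// [[Rcpp::export(name = ".ssaFirstPassage")]]
double ssa_first_passage(NumericVector par, int x0, int y0, int B,
                         double t_max) {
  double t = 0.0, a[5];
  int x = x0, y = y0;
  while (true) {
    propensities(x, y, REAL(par), a);
    const double a0 = a[0] + a[1] + a[2] + a[3] + a[4];
    if (a0 <= 0.0) stop("zero total propensity at (%d, %d)", x, y);
    t += -std::log(unif_rand()) / a0;
    if (t >= t_max) return NA_REAL;
    apply(pick_channel(a, a0), x, y);
    if (x + y > B) return t;
  }
}
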