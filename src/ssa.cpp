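#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact direct-method SSA for the bursty birth-death circuits.
//
// Reaction channels (propensities recomputed after every event):
//   0: X burst   rate k_x                    x += B_x
//   1: X death   rate g_x * x                x -= 1
//   2: Y burst   rate (topology-dependent)   y += B_y
//   3: Y death   rate g_y * y                y -= 1
//   4: Z birth   prop/deriv: k_z*y (burst B_z); integral: k_z*y/<B_z>
//   5: Z death   prop/deriv: g_z*z; integral: constant k_z*y_set (suppressed
//                at z = 0 so counts stay non-negative)
//
// Y-burst frequency by topology (xf = x/xbar when the disturbance is bursty,
// else 1):
//   open:         k_y * xf
//   proportional: k_y * g(z) * xf,  g(z) = 1/(1+(z/z_c)^h)
//   integral:     k_y * g(z) * xf
//   derivative:   k_y * xf * (z/max(y,1))^h
//
// Uses R's RNG stream, so trajectories are reproducible via set.seed().

static inline double sample_burst(int kind, double mean) {
  if (kind == 0) return std::round(mean);        // deterministic
  if (mean <= 1.0) return 1.0;                   // degenerate shifted geometric
  return 1.0 + R::rgeom(1.0 / mean);             // shifted geometric on {1,2,...}
}

// [[Rcpp::export(name = ".ssa_kernel")]]
List ssa_kernel(int topology,
                bool has_x, double k_x, double g_x, int bx_kind,
                double bx_mean, double xbar,
                double k_y, double g_y, int by_kind, double by_mean,
                bool has_z, double k_z, double g_z, int bz_kind,
                double bz_mean,
                double z_c, double hill_h, double y_set,
                double x0, double y0, double z0,
                double t_end, double burn_in,
                bool record, int hist_max, double max_pop,
                double max_events) {
  double x = x0, y = y0, z = z0;
  double t = 0.0;
  double sw = 0.0, sy = 0.0, sy2 = 0.0, sx = 0.0, sz = 0.0;
  std::vector<double> hist;
  if (hist_max > 0) hist.assign(hist_max + 1, 0.0);

  std::vector<double> rt, rx, ry, rz;
  if (record) {
    rt.push_back(t); rx.push_back(x); ry.push_back(y); rz.push_back(z);
  }

  double a[6];
  double n_events = 0.0;

  while (t < t_end) {
    const double xf = has_x ? x / xbar : 1.0;
    a[0] = has_x ? k_x : 0.0;
    a[1] = has_x ? g_x * x : 0.0;
    double yb;
    switch (topology) {
      case 0: yb = k_y * xf; break;                                  // open
      case 1: case 2:                                                // P, I
        yb = k_y * xf / (1.0 + std::pow(z / z_c, hill_h)); break;
      default:                                                       // D
        yb = k_y * xf * std::pow(z / std::max(y, 1.0), hill_h); break;
    }
    a[2] = yb;
    a[3] = g_y * y;
    if (has_z) {
      if (topology == 2) {                                           // integral
        a[4] = k_z * y / bz_mean;
        a[5] = (z > 0.0) ? k_z * y_set : 0.0;
      } else {
        a[4] = k_z * y;
        a[5] = g_z * z;
      }
    } else {
      a[4] = a[5] = 0.0;
    }
    double atot = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
    if (!(atot > 0.0)) {                 // absorbing state: hold to t_end
      double lo = std::max(t, burn_in);
      if (t_end > lo) {
        double w = t_end - lo;
        sw += w; sy += w * y; sy2 += w * y * y; sx += w * x; sz += w * z;
        if (hist_max > 0 && y <= hist_max) hist[(int)y] += w;
      }
      t = t_end;
      break;
    }
    double dt = R::exp_rand() / atot;
    double t_next = t + dt;
    // accumulate time-weighted stats on [t, min(t_next, t_end)) after burn-in
    double hi = std::min(t_next, t_end);
    double lo = std::max(t, burn_in);
    if (hi > lo) {
      double w = hi - lo;
      sw += w; sy += w * y; sy2 += w * y * y; sx += w * x; sz += w * z;
      if (hist_max > 0 && y <= hist_max) hist[(int)y] += w;
    }
    t = t_next;
    if (t >= t_end) break;

    double u = unif_rand() * atot;
    int ev = 0;
    double acc = a[0];
    while (ev < 5 && u > acc) { ++ev; acc += a[ev]; }
    switch (ev) {
      case 0: x += sample_burst(bx_kind, bx_mean); break;
      case 1: x -= 1.0; break;
      case 2: y += sample_burst(by_kind, by_mean); break;
      case 3: y -= 1.0; break;
      case 4: z += sample_burst(bz_kind, bz_mean); break;
      case 5: z -= 1.0; break;
    }
    n_events += 1.0;
    if (x > max_pop || y > max_pop || z > max_pop)
      stop("runaway population: count exceeded cap %g at t = %g "
           "(x=%g, y=%g, z=%g)", max_pop, t, x, y, z);
    if (n_events > max_events)
      stop("event budget exceeded (%g events before t_end = %g); "
           "check rates or raise `max_events`", max_events, t_end);
    if (record) {
      rt.push_back(t); rx.push_back(x); ry.push_back(y); rz.push_back(z);
    }
  }

  List out = List::create(
    _["mean_y"] = sw > 0 ? sy / sw : NA_REAL,
    _["m2_y"] = sw > 0 ? sy2 / sw : NA_REAL,
    _["mean_x"] = sw > 0 ? sx / sw : NA_REAL,
    _["mean_z"] = sw > 0 ? sz / sw : NA_REAL,
    _["weight"] = sw,
    _["n_events"] = n_events,
    _["final"] = NumericVector::create(x, y, z));
  if (hist_max > 0) out["hist"] = NumericVector(hist.begin(), hist.end());
  if (record) {
    out["time"] = NumericVector(rt.begin(), rt.end());
    out["x"] = NumericVector(rx.begin(), rx.end());
    out["y"] = NumericVector(ry.begin(), ry.end());
    out["z"] = NumericVector(rz.begin(), rz.end());
  }
  return out;
}
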