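// Event-driven core of the butterfly movement IBM.
//
// Agents alternate inter-flight (stationary) and flight bouts.  Flight and
// inter-flight durations come from empirical inverse-CDF samplers, flights
// are partitioned into 15-s segments (final remainder shorter), each segment
// gets a von Mises turn and a duration-conditioned step length completed at
// constant speed over the segment, and one further turn is applied at flight
// end.  Habitat lookups use the agent's instantaneous (toroidally wrapped)
// position; all samplers arrive pre-resolved per habitat class, so pooled
// parameterizations simply supply the same sampler for both classes.
//
// All randomness flows through R's RNG (unif_rand), so runs are reproducible
// under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double SEG_S = 15.0;     // turn/step cadence during flight
static const double KAPPA_DEGEN = 1e6; // point-mass cutoff for von Mises

static double wrap_pi(double th) {
  double z = (th + M_PI) / (2.0 * M_PI);
  th = (z - std::floor(z)) * 2.0 * M_PI;
  return th - M_PI;
}

// inverse-ECDF linear interpolation on a sorted sample
static double ecdf_draw(const NumericVector& y, double u) {
  int n = y.size();
  if (n == 1) return y[0];
  double pos = u * (n - 1);
  int i = (int)std::floor(pos);
  if (i > n - 2) i = n - 2;
  double f = pos - i;
  return y[i] + f * (y[i + 1] - y[i]);
}

// Best-Fisher (1979) von Mises sampler; kappa >= 1e6 degenerates to mu
static double vm_draw(double mu, double kappa) {
  if (kappa >= KAPPA_DEGEN) return mu;
  if (kappa < 1e-8) return (2.0 * unif_rand() - 1.0) * M_PI;
  double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  double r = (1.0 + b * b) / (2.0 * b);
  double f;
  for (;;) {
    double u1 = unif_rand(), u2 = unif_rand();
    double z = std::cos(M_PI * u1);
    f = (1.0 + r * z) / (r + z);
    double c = kappa * (r - f);
    if (c * (2.0 - c) > u2) break;
    if (u2 > 0 && std::log(c / u2) + 1.0 - c >= 0.0) break;
  }
  if (f > 1.0) f = 1.0; else if (f < -1.0) f = -1.0;
  double th = (unif_rand() > 0.5 ? 1.0 : -1.0) * std::acos(f) + mu;
  return wrap_pi(th);
}

// k-nearest-duration step draw; ties prefer the smaller duration
static double knn_step(const NumericVector& dur, const NumericVector& len,
                       int k, double d, double u) {
  int n = dur.size();
  if (k > n) k = n;
  int lo = (int)(std::lower_bound(dur.begin(), dur.end(), d) - dur.begin());
  int l = lo - 1, r = lo;
  for (int taken = 0; taken < k; ++taken) {
    if (l < 0) ++r;
    else if (r >= n) --l;
    else if (d - dur[l] <= dur[r] - d) --l;
    else ++r;
  }
  int j = (int)std::floor(u * k);
  if (j >= k) j = k - 1;
  return len[l + 1 + j];
}

struct HabitatMap {
  bool fixed;
  int fixed_class;
  const int* grid; // n x n, column-major, rows index x
  int n;
  double cell;
  int at(double x, double y) const {
    if (fixed) return fixed_class;
    int ix = (int)std::floor(x / cell) % n; if (ix < 0) ix += n;
    int iy = (int)std::floor(y / cell) % n; if (iy < 0) iy += n;
    return grid[ix + (size_t)n * iy];
  }
};

// [[Rcpp::export]]
NumericVector ibm_run_cpp(List flight, List inter, List step_dur, List step_len,
                          NumericVector turn_mu, NumericVector turn_kappa,
                          int k,
                          Nullable<IntegerMatrix> grid_, double cell_size,
                          double side_m, int fixed_habitat,
                          int n_agents, double active_s, double burnin_s) {
  NumericVector fl[2] = { as<NumericVector>(flight[0]), as<NumericVector>(flight[1]) };
  NumericVector itf[2] = { as<NumericVector>(inter[0]), as<NumericVector>(inter[1]) };
  NumericVector sd[2] = { as<NumericVector>(step_dur[0]), as<NumericVector>(step_dur[1]) };
  NumericVector sl[2] = { as<NumericVector>(step_len[0]), as<NumericVector>(step_len[1]) };

  HabitatMap hm;
  IntegerMatrix grid;
  if (grid_.isNotNull()) {
    grid = grid_.get();
    hm.fixed = false; hm.fixed_class = 0;
    hm.grid = grid.begin(); hm.n = grid.nrow(); hm.cell = cell_size;
  } else {
    hm.fixed = true; hm.fixed_class = fixed_habitat;
    hm.grid = nullptr; hm.n = 1; hm.cell = 1.0;
  }

  const double total = burnin_s + active_s;
  const long max_events = 500000000L; // guard against degenerate inputs
  NumericVector out(n_agents);

  for (int a = 0; a < n_agents; ++a) {
    double x, y;
    if (hm.fixed) { x = 0.0; y = 0.0; }
    else { x = unif_rand() * side_m; y = unif_rand() * side_m; }
    double heading = (2.0 * unif_rand() - 1.0) * M_PI;
    double t = 0.0;
    bool anchored = false;
    double ax = x, ay = y;
    if (burnin_s <= 0.0) { anchored = true; }
    long events = 0;
    bool done = false;
    while (!done) {
      if (++events > max_events) stop("ibm_run_cpp: event limit exceeded (degenerate samplers?)");
      // inter-flight: position unchanged
      int h = hm.at(x, y);
      double d = ecdf_draw(itf[h], unif_rand());
      if (!anchored && t + d >= burnin_s) { ax = x; ay = y; anchored = true; }
      t += d;
      if (t >= total) break;
      // flight
      h = hm.at(x, y);
      double T = ecdf_draw(fl[h], unif_rand());
      double rem = T;
      while (rem > 1e-12) {
        if (++events > max_events) stop("ibm_run_cpp: event limit exceeded");
        double seg = rem < SEG_S ? rem : SEG_S;
        int hmv = hm.at(x, y);
        heading = wrap_pi(heading + vm_draw(turn_mu[hmv], turn_kappa[hmv]));
        double L = knn_step(sd[hmv], sl[hmv], k, seg, unif_rand());
        double v = seg > 0 ? L / seg : 0.0;
        double cs = std::cos(heading), sn = std::sin(heading);
        double dt = seg;
        if (t + dt >= total) {
          dt = total - t;
          if (!anchored && burnin_s <= t + dt) {
            double d1 = burnin_s - t;
            ax = x + v * d1 * cs; ay = y + v * d1 * sn;
            anchored = true;
          }
          x += v * dt * cs; y += v * dt * sn;
          t = total;
          done = true;
          break;
        }
        if (!anchored && t + dt >= burnin_s) {
          double d1 = burnin_s - t;
          ax = x + v * d1 * cs; ay = y + v * d1 * sn;
          anchored = true;
        }
        x += v * seg * cs; y += v * seg * sn;
        t += seg;
        rem -= seg;
      }
      if (done) break;
      // post-flight turn
      int hp = hm.at(x, y);
      heading = wrap_pi(heading + vm_draw(turn_mu[hp], turn_kappa[hp]));
    }
    if (!anchored) { ax = x; ay = y; } // run ended inside burn-in
    out[a] = std::hypot(x - ax, y - ay);
  }
  return out;
}
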