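#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.0083144626; // kJ/(mol K)

// Gaussian-well model potential: F(x) = -sum_i A_i exp(-|x-c_i|^2/(2 w_i^2))
//                                       + 0.5 k |x - cc|^2
// Energy and gradient accumulated into E, g (g must be zeroed by caller).
static inline void pot_eg(const NumericMatrix &C, const NumericVector &A,
                          const NumericVector &W, const NumericVector &cc,
                          double ck, const double *x, int d, double &E,
                          double *g) {
  E = 0.0;
  for (int j = 0; j < d; ++j) g[j] = 0.0;
  const int n = C.nrow();
  for (int i = 0; i < n; ++i) {
    double r2 = 0.0;
    for (int j = 0; j < d; ++j) {
      const double dx = x[j] - C(i, j);
      r2 += dx * dx;
    }
    const double w2 = W[i] * W[i];
    const double e = A[i] * std::exp(-r2 / (2.0 * w2));
    E -= e;
    for (int j = 0; j < d; ++j) g[j] += e * (x[j] - C(i, j)) / w2;
  }
  if (ck > 0.0) {
    for (int j = 0; j < d; ++j) {
      const double dx = x[j] - cc[j];
      E += 0.5 * ck * dx * dx;
      g[j] += ck * dx;
    }
  }
}

// Bias potential and gradient from deposited hills (shared widths `sig`),
// 6-sigma cutoff per dimension. Adds into g.
static inline double bias_eg(const std::vector<double> &hc,
                             const std::vector<double> &hh,
                             const double *sig, int d, const double *x,
                             double *g, bool want_grad) {
  double V = 0.0;
  const int nh = (int)hh.size();
  for (int h = 0; h < nh; ++h) {
    double arg = 0.0;
    bool skip = false;
    for (int j = 0; j < d; ++j) {
      const double dx = x[j] - hc[(size_t)h * d + j];
      if (std::fabs(dx) > 6.0 * sig[j]) { skip = true; break; }
      arg += dx * dx / (2.0 * sig[j] * sig[j]);
    }
    if (skip) continue;
    const double e = hh[h] * std::exp(-arg);
    V += e;
    if (want_grad)
      for (int j = 0; j < d; ++j) {
        const double dx = x[j] - hc[(size_t)h * d + j];
        g[j] += -e * dx / (sig[j] * sig[j]);
      }
  }
  return V;
}

// Overdamped Langevin propagation on a Gaussian-well potential, optionally
// depositing well-tempered metadynamics hills every `stride_steps` steps.
// Euler-Maruyama: x += -(dt/friction) * grad(F+V) + sqrt(2 kB T dt/friction) * xi
// W0 <= 0 or stride_steps <= 0 disables deposition (plain Langevin).
// Uses the R RNG so set.seed() in R controls the stream.
// [[Rcpp::export]]
List cpp_langevin_metad(NumericMatrix centers, NumericVector depths,
                        NumericVector widths, NumericVector conf_center,
                        double conf_k, NumericVector x0, double friction,
                        double temperature, double dt, int n_steps,
                        int save_stride, double W0, NumericVector sigma,
                        int stride_steps, double biasfactor, bool reflect,
                        double wall_lo) {
  const int d = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> g(d), hc, hh;
  std::vector<double> ht; // deposition times
  const double kBT = KB * temperature;
  const double mob = dt / friction;
  const double noise = std::sqrt(2.0 * kBT * dt / friction);
  const bool metad = (W0 > 0.0 && stride_steps > 0);
  const double kBdT = metad ? KB * (biasfactor - 1.0) * temperature : 1.0;

  const int n_save = n_steps / save_stride;
  NumericMatrix pos(n_save, d);
  NumericVector tsave(n_save);
  int isave = 0;
  double E;

  for (int step = 1; step <= n_steps; ++step) {
    pot_eg(centers, depths, widths, conf_center, conf_k, x.data(), d, E,
           g.data());
    if (metad && !hh.empty())
      bias_eg(hc, hh, sigma.begin(), d, x.data(), g.data(), true);
    for (int j = 0; j < d; ++j) {
      if (!std::isfinite(g[j]))
        stop("non-finite force at step %d (CV %d)", step, j + 1);
      x[j] += -mob * g[j] + noise * norm_rand();
      if (reflect && x[j] < wall_lo) x[j] = 2.0 * wall_lo - x[j];
    }
    if (metad && step % stride_steps == 0) {
      const double V =
          hh.empty() ? 0.0
                     : bias_eg(hc, hh, sigma.begin(), d, x.data(), g.data(),
                               false);
      const double W = W0 * std::exp(-V / kBdT);
      for (int j = 0; j < d; ++j) hc.push_back(x[j]);
      hh.push_back(W);
      ht.push_back(step * dt);
    }
    if (step % save_stride == 0) {
      for (int j = 0; j < d; ++j) pos(isave, j) = x[j];
      tsave[isave] = step * dt;
      ++isave;
    }
  }

  const int nh = (int)hh.size();
  NumericMatrix hcenters(nh, d);
  NumericVector hheights(nh), htimes(nh);
  for (int h = 0; h < nh; ++h) {
    for (int j = 0; j < d; ++j) hcenters(h, j) = hc[(size_t)h * d + j];
    hheights[h] = hh[h];
    htimes[h] = ht[h];
  }
  return List::create(_["positions"] = pos, _["times"] = tsave,
                      _["hill_times"] = htimes, _["hill_centers"] = hcenters,
                      _["hill_heights"] = hheights);
}

// Sum of Gaussian hills evaluated on a rectilinear grid (1D or 2D),
// separable-exponential factorisation per hill. Heights and per-hill widths
// given explicitly; returns V on the grid (vector, dim set in R).
// [[Rcpp::export]]
NumericVector cpp_bias_sum_grid(NumericMatrix hcenters, NumericMatrix hsigmas,
                                NumericVector hheights, List axes) {
  const int d = axes.size();
  const int nh = hcenters.nrow();
  if (d == 1) {
    NumericVector ax = axes[0];
    const int nx = ax.size();
    NumericVector V(nx);
    for (int h = 0; h < nh; ++h) {
      const double c = hcenters(h, 0), s2 = 2.0 * hsigmas(h, 0) * hsigmas(h, 0);
      const double w = hheights[h];
      for (int i = 0; i < nx; ++i) {
        const double dx = ax[i] - c;
        V[i] += w * std::exp(-dx * dx / s2);
      }
    }
    return V;
  } else if (d == 2) {
    NumericVector ax = axes[0], ay = axes[1];
    const int nx = ax.size(), ny = ay.size();
    NumericVector V(nx * ny);
    std::vector<double> ex(nx), ey(ny);
    for (int h = 0; h < nh; ++h) {
      const double cx = hcenters(h, 0), cy = hcenters(h, 1);
      const double sx2 = 2.0 * hsigmas(h, 0) * hsigmas(h, 0);
      const double sy2 = 2.0 * hsigmas(h, 1) * hsigmas(h, 1);
      const double w = hheights[h];
      for (int i = 0; i < nx; ++i) {
        const double dx = ax[i] - cx;
        ex[i] = std::exp(-dx * dx / sx2);
      }
      for (int j = 0; j < ny; ++j) {
        const double dy = ay[j] - cy;
        ey[j] = std::exp(-dy * dy / sy2);
      }
      for (int j = 0; j < ny; ++j) {
        const double wy = w * ey[j];
        if (wy < 1e-300) continue;
        double *col = &V[(size_t)j * nx];
        for (int i = 0; i < nx; ++i) col[i] += wy * ex[i];
      }
    }
    return V;
  }
  stop("only 1D and 2D grids are supported");
}
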