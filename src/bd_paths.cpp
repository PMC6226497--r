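// Euler-Maruyama Brownian dynamics on a 1D free-energy surface with
// absorbing boundaries, used to generate transition paths: trajectories are
// launched at x0 + eps and only those absorbed at x1 without first returning
// to x0 are retained. Within-step boundary crossings are detected with the
// standard Brownian-bridge correction, which removes the leading
// discretization bias of first-passage times.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double interp_drift(const arma::vec& xg, const arma::vec& fg,
                                  double x) {
  // uniform grid linear interpolation
  const double x0 = xg(0), dx = xg(1) - xg(0);
  double u = (x - x0) / dx;
  int i = (int)std::floor(u);
  if (i < 0) i = 0;
  int n = (int)xg.n_elem;
  if (i > n - 2) i = n - 2;
  double w = u - i;
  return fg(i) * (1.0 - w) + fg(i + 1) * w;
}

// xg, drift: uniform grid on [x0, x1] and the drift -D * dV/dx (beta = 1)
// evaluated on it; D: diffusion coefficient (coordinate^2/s); dt: time step
// (s); eps: launch offset from x0; nPaths: number of successful transition
// paths required; maxLaunch: give up (error) after this many launches;
// nStore: store full position records for the first nStore successes.
// Uses R's RNG (respects set.seed()).
// [[Rcpp::export]]
List cpp_bd_paths(const arma::vec& xg, const arma::vec& drift, double D,
                  double dt, double eps, int nPaths, double maxLaunch,
                  int nStore) {
  const double x0 = xg(0), x1 = xg(xg.n_elem - 1);
  const double sig = std::sqrt(2.0 * D * dt);
  arma::vec durations(nPaths);
  List stored(nStore);
  int nsucc = 0;
  double nlaunch = 0;
  std::vector<double> buf;
  const bool storing0 = nStore > 0;
  while (nsucc < nPaths) {
    if (++nlaunch > maxLaunch)
      stop("BD success rate too low (%d successes in %.0f launches); "
           "consider a larger launch offset eps", nsucc, nlaunch);
    double x = x0 + eps;
    bool store_this = storing0 && nsucc < nStore;
    if (store_this) { buf.clear(); buf.push_back(x); }
    long step = 0;
    for (;;) {
      ++step;
      double xp = x;
      x += interp_drift(xg, drift, x) * dt + sig * norm_rand();
      bool hit1 = x >= x1, hit0 = x <= x0;
      if (!hit1 && !hit0) {
        // Brownian-bridge probability of an unobserved excursion past a
        // boundary within the step
        double p1 = std::exp(-2.0 * (x1 - xp) * (x1 - x) / (2.0 * D * dt));
        if (unif_rand() < p1) hit1 = true;
        else {
          double p0 = std::exp(-2.0 * (xp - x0) * (x - x0) / (2.0 * D * dt));
          if (unif_rand() < p0) hit0 = true;
        }
      }
      if (hit1) {
        durations(nsucc) = step * dt;
        if (store_this) {
          buf.push_back(x1);
          stored[nsucc] = NumericVector(buf.begin(), buf.end());
        }
        ++nsucc;
        break;
      }
      if (hit0) break;  // returned to the unbound boundary: not a transition path
      if (store_this) buf.push_back(x);
      if (step % 4096 == 0) Rcpp::checkUserInterrupt();
    }
  }
  return List::create(Named("durations") = durations,
                      Named("launches") = nlaunch,
                      Named("paths") = stored);
}
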