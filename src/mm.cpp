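#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// Tukey bisquare rho, normalised so rho(inf) = c^2/6.
static inline double rho_bisq(double u, double c) {
  double a = std::fabs(u);
  if (a >= c) return c * c / 6.0;
  double t = 1.0 - (u / c) * (u / c);
  return (c * c / 6.0) * (1.0 - t * t * t);
}

// Bisquare weight psi(u)/u.
static inline double w_bisq(double u, double c) {
  double a = std::fabs(u);
  if (a >= c) return 0.0;
  double t = 1.0 - (u / c) * (u / c);
  return t * t;
}

// Solve the M-scale equation (1/n) sum rho(r_i/s, c) = b for s by
// fixed-point iteration s^2 <- s^2 * mean(rho)/b.
static double m_scale(const std::vector<double>& r, double c, double b,
                      double s0) {
  const int n = r.size();
  double s = s0;
  if (s <= 0.0) {
    // start from the normalised median absolute residual
    std::vector<double> a(n);
    for (int i = 0; i < n; ++i) a[i] = std::fabs(r[i]);
    std::nth_element(a.begin(), a.begin() + n / 2, a.end());
    s = a[n / 2] / 0.6745;
    if (s <= 0.0) {
      double mx = 0.0;
      for (int i = 0; i < n; ++i) mx = std::max(mx, std::fabs(r[i]));
      if (mx == 0.0) return 0.0;
      s = mx;
    }
  }
  for (int it = 0; it < 80; ++it) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += rho_bisq(r[i] / s, c);
    m /= n;
    if (m <= 0.0) return 0.0;
    double snew = s * std::sqrt(m / b);
    if (std::fabs(snew - s) <= 1e-10 * s) return snew;
    s = snew;
  }
  return s;
}

// Weighted least-squares line through (x, y).
static void wls(const std::vector<double>& x, const std::vector<double>& y,
                const std::vector<double>& w, double& slope, double& inter) {
  const int n = x.size();
  double sw = 0, sx = 0, sy = 0, sxx = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    sw += w[i];
    sx += w[i] * x[i];
    sy += w[i] * y[i];
    sxx += w[i] * x[i] * x[i];
    sxy += w[i] * x[i] * y[i];
  }
  double den = sw * sxx - sx * sx;
  if (sw <= 0.0 || std::fabs(den) < 1e-300) return;  // keep previous values
  slope = (sw * sxy - sx * sy) / den;
  inter = (sy - slope * sx) / sw;
}

// MM-type robust simple regression of y on x.
//
// Stage 1 (S): `n_sub` seeded two-point subsamples propose candidate lines;
// each candidate's 50%-breakdown bisquare M-scale (tuning c_s) of residuals
// is computed, with an early rejection test against the best scale so far;
// the winner is refined by iterated reweighted least squares with
// simultaneous scale updates until the S-objective stabilises.
// Stage 2 (M): IRLS with bisquare weights at tuning c_m and the scale held
// fixed from stage 1, run from the S-coefficients until the maximum
// relative coefficient change drops below `tol` or `max_iter` iterations.
// [[Rcpp::export(name = ".mm_fit_cpp")]]
List mm_fit_cpp(NumericVector xr, NumericVector yr, int n_sub, int seed,
                double c_s, double c_m, double tol, int max_iter) {
  const int n = xr.size();
  if ((int)yr.size() != n) stop("x and y lengths differ");
  std::vector<double> x(xr.begin(), xr.end()), y(yr.begin(), yr.end());
  const double b_s = 0.5 * c_s * c_s / 6.0;  // 50% breakdown consistency

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_int_distribution<int> pick(0, n - 1);

  double best_slope = 0.0, best_inter = 0.0, best_s = -1.0;
  std::vector<double> r(n);

  for (int k = 0; k < n_sub; ++k) {
    int i = pick(rng), j = pick(rng);
    if (i == j || x[i] == x[j]) continue;  // degenerate draw, try next
    double slope = (y[j] - y[i]) / (x[j] - x[i]);
    double inter = y[i] - slope * x[i];
    for (int t = 0; t < n; ++t) r[t] = y[t] - inter - slope * x[t];
    if (best_s > 0.0) {
      // early rejection: mean rho at the current best scale
      double m = 0.0;
      for (int t = 0; t < n; ++t) m += rho_bisq(r[t] / best_s, c_s);
      if (m / n > b_s) continue;  // implied scale exceeds best
    }
    double s = m_scale(r, c_s, b_s, best_s);
    if (s >= 0.0 && (best_s < 0.0 || s < best_s)) {
      best_s = s;
      best_slope = slope;
      best_inter = inter;
    }
  }
  if (best_s < 0.0) stop("S-estimator found no valid subsample (x constant?)");

  // refine the S-candidate: IRLS with scale updates
  double slope = best_slope, inter = best_inter, s = best_s;
  if (s > 0.0) {
    std::vector<double> w(n);
    for (int it = 0; it < 50; ++it) {
      for (int t = 0; t < n; ++t) r[t] = y[t] - inter - slope * x[t];
      s = m_scale(r, c_s, b_s, s);
      if (s <= 0.0) break;
      for (int t = 0; t < n; ++t) w[t] = w_bisq(r[t] / s, c_s);
      double sl = slope, in = inter;
      wls(x, y, w, sl, in);
      double ch = std::max(std::fabs(sl - slope), std::fabs(in - inter));
      slope = sl;
      inter = in;
      if (ch < 1e-10 * std::max(1.0, std::fabs(slope))) break;
    }
    for (int t = 0; t < n; ++t) r[t] = y[t] - inter - slope * x[t];
    s = m_scale(r, c_s, b_s, s);
  }

  // exact fit: scale zero, nothing to reweight
  bool converged = true;
  int n_iter = 0;
  if (s > 0.0) {
    std::vector<double> w(n);
    converged = false;
    for (; n_iter < max_iter; ++n_iter) {
      for (int t = 0; t < n; ++t) r[t] = y[t] - inter - slope * x[t];
      for (int t = 0; t < n; ++t) w[t] = w_bisq(r[t] / s, c_m);
      double sl = slope, in = inter;
      wls(x, y, w, sl, in);
      double rel = std::max(
          std::fabs(sl - slope) / std::max(std::fabs(slope), 1e-10),
          std::fabs(in - inter) / std::max(std::fabs(inter), 1e-10));
      slope = sl;
      inter = in;
      if (rel < tol) {
        converged = true;
        ++n_iter;
        break;
      }
    }
  }

  for (int t = 0; t < n; ++t) r[t] = y[t] - inter - slope * x[t];
  NumericVector wout(n), rout(n);
  for (int t = 0; t < n; ++t) {
    wout[t] = (s > 0.0) ? w_bisq(r[t] / s, c_m) : 1.0;
    rout[t] = r[t];
  }

  return List::create(_["slope"] = slope, _["intercept"] = inter,
                      _["scale"] = s, _["weights"] = wout,
                      _["residuals"] = rout, _["converged"] = converged,
                      _["n_iter"] = n_iter);
}
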