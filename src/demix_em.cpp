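#include <Rcpp.h>
using namespace Rcpp;

// positive remainder modulo 180 without std::fmod
static inline double wrap180(double x) {
  return x - 180.0 * std::floor(x / 180.0);
}

// Wrapped-normal density on the 180-degree orientation circle, direct wrap
// sum; wrap terms beyond 8.5 SDs (relative contribution < 1e-15) are skipped.
static inline double wn_dens(double x, double mu, double sigma) {
  double d = wrap180(x - mu);
  int kmax = std::max(2, (int)std::ceil(6.0 * sigma / 180.0) + 1);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double norm = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  double cut = 8.5 * sigma;
  double out = 0.0;
  for (int k = -kmax; k <= kmax; ++k) {
    double z = d + 180.0 * k;
    if (z > cut || z < -cut) continue;
    out += std::exp(-z * z * inv2s2);
  }
  return out * norm;
}

static inline double norm_dens(double x, double mu, double sigma) {
  double z = (x - mu) / sigma;
  return std::exp(-0.5 * z * z) / (sigma * std::sqrt(2.0 * M_PI));
}

struct DmTheta {
  double pi1;
  double mu1[2], sigma1[2];  // orientation dimension (deg, wrapped)
  double mu2[2], sigma2;     // temporal dimension (shared SD)
  double loglik;
  bool converged;
  bool monotone;
  int iters;
};

// One EM run from a given initial responsibility vector (P(comp 1 | x_i)).
static DmTheta em_one(const double* x1, const double* x2, int n,
                      const double* init_r, double tol, int max_iter,
                      double floor_ori, double floor_temp,
                      bool pin_pi, double pi_fixed) {
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = init_r[i];

  DmTheta th;
  th.loglik = -std::numeric_limits<double>::infinity();
  th.converged = false;
  th.monotone = true;
  th.iters = 0;

  double prev_ll = -std::numeric_limits<double>::infinity();
  const double deg2rad2 = M_PI / 90.0;  // doubled-angle radians per degree

  for (int iter = 0; iter < max_iter; ++iter) {
    // ---- M-step from current responsibilities ----
    double w1 = 0.0;
    for (int i = 0; i < n; ++i) w1 += r[i];
    double w2 = n - w1;
    if (w1 < 1e-8) w1 = 1e-8;
    if (w2 < 1e-8) w2 = 1e-8;

    double pi1 = pin_pi ? pi_fixed : w1 / n;
    if (pi1 < 1e-6) pi1 = 1e-6;
    if (pi1 > 1.0 - 1e-6) pi1 = 1.0 - 1e-6;

    double mu1[2], s1[2], mu2[2];
    for (int j = 0; j < 2; ++j) {
      double C = 0.0, S = 0.0, m2 = 0.0, wj = (j == 0) ? w1 : w2;
      for (int i = 0; i < n; ++i) {
        double rij = (j == 0) ? r[i] : 1.0 - r[i];
        double phi = x1[i] * deg2rad2;
        C += rij * std::cos(phi);
        S += rij * std::sin(phi);
        m2 += rij * x2[i];
      }
      mu1[j] = wrap180(std::atan2(S, C) * 90.0 / M_PI);
      double Rbar = std::sqrt(C * C + S * S) / wj;
      if (Rbar > 1.0 - 1e-12) Rbar = 1.0 - 1e-12;
      if (Rbar < 1e-12) Rbar = 1e-12;
      double sd = std::sqrt(-2.0 * std::log(Rbar)) * 90.0 / M_PI;
      s1[j] = std::max(sd, floor_ori);
      mu2[j] = m2 / wj;
    }
    // pooled temporal SD (shared across components)
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double d1 = x2[i] - mu2[0], d2 = x2[i] - mu2[1];
      ss += r[i] * d1 * d1 + (1.0 - r[i]) * d2 * d2;
    }
    double s2 = std::max(std::sqrt(ss / n), floor_temp);

    // ---- E-step and log-likelihood ----
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double f1 = pi1 * wn_dens(x1[i], mu1[0], s1[0]) * norm_dens(x2[i], mu2[0], s2);
      double f2 = (1.0 - pi1) * wn_dens(x1[i], mu1[1], s1[1]) * norm_dens(x2[i], mu2[1], s2);
      double tot = f1 + f2;
      if (tot < 1e-300) tot = 1e-300;
      r[i] = f1 / tot;
      ll += std::log(tot);
    }

    th.pi1 = pi1;
    th.mu1[0] = mu1[0]; th.mu1[1] = mu1[1];
    th.sigma1[0] = s1[0]; th.sigma1[1] = s1[1];
    th.mu2[0] = mu2[0]; th.mu2[1] = mu2[1];
    th.sigma2 = s2;
    th.loglik = ll;
    th.iters = iter + 1;

    // the resultant-inversion M-step approximates the exact wrapped-normal
    // MLE, so tiny decreases (observed < 0.05 units) are numerical slack
    if (std::isfinite(prev_ll) && ll < prev_ll - 0.05) th.monotone = false;
    if (std::isfinite(prev_ll) && std::fabs(ll - prev_ll) < tol) {
      th.converged = true;
      break;
    }
    prev_ll = ll;
  }
  return th;
}

// Order components so the one with the larger temporal mean is first.
static void order_theta(DmTheta& th) {
  if (th.mu2[1] > th.mu2[0]) {
    std::swap(th.mu1[0], th.mu1[1]);
    std::swap(th.sigma1[0], th.sigma1[1]);
    std::swap(th.mu2[0], th.mu2[1]);
    th.pi1 = 1.0 - th.pi1;
  }
}

// Multi-restart EM fit for the two-component orientation x time mixture.
// init_resp: n x n_restarts matrix of initial P(comp 1) responsibilities.
// [[Rcpp::export]]
List dm_em_cpp(NumericVector x1, NumericVector x2, NumericMatrix init_resp,
               double tol, int max_iter, double floor_ori, double floor_temp,
               bool pin_pi, double pi_fixed) {
  int n = x1.size();
  int R = init_resp.ncol();
  if (x2.size() != n || init_resp.nrow() != n)
    stop("dimension mismatch in dm_em_cpp");

  DmTheta best;
  best.loglik = -std::numeric_limits<double>::infinity();
  best.converged = false;
  best.monotone = true;
  int n_conv = 0;
  bool any_nonmonotone = false;

  for (int s = 0; s < R; ++s) {
    DmTheta th = em_one(&x1[0], &x2[0], n, &init_resp(0, s), tol, max_iter,
                        floor_ori, floor_temp, pin_pi, pi_fixed);
    if (!th.monotone) any_nonmonotone = true;
    if (th.converged) ++n_conv;
    if (th.loglik > best.loglik) best = th;
  }
  order_theta(best);

  return List::create(
    _["pi1"] = best.pi1,
    _["mu_ori"] = NumericVector::create(best.mu1[0], best.mu1[1]),
    _["sigma_ori"] = NumericVector::create(best.sigma1[0], best.sigma1[1]),
    _["mu_temp"] = NumericVector::create(best.mu2[0], best.mu2[1]),
    _["sigma_temp"] = best.sigma2,
    _["loglik"] = best.loglik,
    _["converged"] = best.converged,
    _["n_converged"] = n_conv,
    _["n_restarts_used"] = R,
    _["iters"] = best.iters,
    _["monotone"] = !any_nonmonotone,
    _["degenerate"] = (best.sigma1[0] <= floor_ori + 1e-12 ||
                       best.sigma1[1] <= floor_ori + 1e-12));
}

// Fit every trial of a simulation cell and return the demixing-model
// response (orientation mean of the temporally later component) per trial.
// x1mat, x2mat: N x n_trials; init_arr: N x (n_restarts * n_trials).
// [[Rcpp::export]]
List dm_cell_cpp(NumericMatrix x1mat, NumericMatrix x2mat, NumericMatrix init_arr,
                 int n_restarts, double tol, int max_iter,
                 double floor_ori, double floor_temp,
                 bool pin_pi, double pi_fixed) {
  int n = x1mat.nrow();
  int T = x1mat.ncol();
  if (init_arr.nrow() != n || init_arr.ncol() != n_restarts * T)
    stop("init_arr dimension mismatch");

  NumericVector resp(T);
  IntegerVector conv(T);
  for (int t = 0; t < T; ++t) {
    DmTheta best;
    best.loglik = -std::numeric_limits<double>::infinity();
    best.converged = false;
    int n_conv = 0;
    for (int s = 0; s < n_restarts; ++s) {
      DmTheta th = em_one(&x1mat(0, t), &x2mat(0, t), n,
                          &init_arr(0, t * n_restarts + s), tol, max_iter,
                          floor_ori, floor_temp, pin_pi, pi_fixed);
      if (th.converged) ++n_conv;
      if (th.loglik > best.loglik) best = th;
    }
    order_theta(best);
    resp[t] = best.mu1[0];
    conv[t] = n_conv;
  }
  return List::create(_["response"] = resp, _["n_converged"] = conv);
}
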