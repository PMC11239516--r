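// Four-component mixture EM with soft labels for the pair-correlation
// distance distribution: uniform background (interfork pairs),
// exponential + half-normal (intrapulse pairs), normal (interpulse
// pairs, the speed component).  M-step uses weighted means for the
// exponential and normal components and weighted variances for the
// half-normal and normal components.  The exponential mean is
// constrained to > 1000 bp and its prior probability to >= 0.01.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double SQRT_2_OVER_PI = 0.7978845608028654;

// [[Rcpp::export(name = ".mixture_em")]]
List mixture_em(NumericVector x, double upper,
                NumericVector w0, double exp_mean0, double hn_sd0,
                double norm_mean0, double norm_sd0,
                int max_iter = 100, double tol = 1e-8,
                double exp_mean_floor = 1000.0, double pi_exp_floor = 0.01) {
  const int n = x.size();
  if (n == 0) stop("no distances to fit");
  double w[4] = {w0[0], w0[1], w0[2], w0[3]};
  double em = std::max(exp_mean0, exp_mean_floor + 1e-6);
  double hs = hn_sd0, nm = norm_mean0, ns = norm_sd0;

  std::vector<double> r0(n), r1(n), r2(n), r3(n);
  std::vector<double> llt;
  double ll_old = R_NegInf;
  bool converged = false, collapsed = false;
  int it = 0;
  const double dunif = 1.0 / upper;

  for (it = 1; it <= max_iter; ++it) {
    // E-step
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double xi = x[i];
      double f0 = w[0] * dunif;
      double f1 = w[1] * (1.0 / em) * std::exp(-xi / em);
      double f2 = w[2] * (SQRT_2_OVER_PI / hs) *
                  std::exp(-xi * xi / (2.0 * hs * hs));
      double z = (xi - nm) / ns;
      double f3 = w[3] * std::exp(-0.5 * z * z) /
                  (ns * 2.5066282746310002);
      double tot = f0 + f1 + f2 + f3;
      if (tot <= 0 || !R_FINITE(tot)) tot = 1e-300;
      r0[i] = f0 / tot; r1[i] = f1 / tot; r2[i] = f2 / tot; r3[i] = f3 / tot;
      ll += std::log(tot);
    }
    llt.push_back(ll);
    if (R_FINITE(ll_old) &&
        std::fabs(ll - ll_old) <= tol * std::fabs(ll_old)) {
      converged = true;
      break;
    }
    ll_old = ll;

    // M-step
    double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
    double sx1 = 0, sx3 = 0, sxx2 = 0;
    for (int i = 0; i < n; ++i) {
      s0 += r0[i]; s1 += r1[i]; s2 += r2[i]; s3 += r3[i];
      sx1 += r1[i] * x[i];
      sx3 += r3[i] * x[i];
      sxx2 += r2[i] * x[i] * x[i];
    }
    w[0] = s0 / n; w[1] = s1 / n; w[2] = s2 / n; w[3] = s3 / n;
    if (s1 > 0) em = sx1 / s1;
    if (s2 > 0) hs = std::sqrt(sxx2 / s2);
    if (s3 > 0) {
      nm = sx3 / s3;
      double sv = 0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - nm;
        sv += r3[i] * d * d;
      }
      ns = std::sqrt(sv / s3);
    }
    // constraint projection
    if (em <= exp_mean_floor) em = exp_mean_floor + 1e-6;
    if (w[1] < pi_exp_floor) {
      double others = w[0] + w[2] + w[3];
      double scale = (1.0 - pi_exp_floor) / others;
      w[0] *= scale; w[2] *= scale; w[3] *= scale;
      w[1] = pi_exp_floor;
    }
    // numerical guards
    if (hs < 10.0) hs = 10.0;
    if (ns < 10.0 || nm <= 0 || w[3] < 1e-6) collapsed = true;
    if (ns < 10.0) ns = 10.0;
    if (nm <= 0) nm = 1.0;
  }
  if (it > max_iter) it = max_iter;

  return List::create(
    _["weights"] = NumericVector::create(w[0], w[1], w[2], w[3]),
    _["exp_mean"] = em, _["halfnormal_sd"] = hs,
    _["normal_mean"] = nm, _["normal_sd"] = ns,
    _["loglik"] = NumericVector(llt.begin(), llt.end()),
    _["n_iter"] = it, _["converged"] = converged,
    _["collapsed"] = collapsed);
}
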