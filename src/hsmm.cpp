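// Explicit-duration two-state hidden semi-Markov model on inter-read
// distances.  States alternate (foreground <-> background); emissions
// are exponential (log-densities precomputed in R); sojourn pmfs are
// discretised gamma on durations 1..Dmax (log pmf precomputed in R).
// Log-space forward/backward supplies the EM sufficient statistics;
// Viterbi decodes the track segmentation.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logsumexp(const std::vector<double>& v) {
  double m = R_NegInf;
  for (double x : v) if (x > m) m = x;
  if (!R_FINITE(m)) return R_NegInf;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// logf: T x 2 emission log-densities; logdur: Dmax x 2 sojourn log-pmf;
// logpi: length-2 initial log-probabilities; x: observations (for the
// emission sufficient statistics).
// [[Rcpp::export(name = ".hsmm_estep")]]
List hsmm_estep(NumericVector x, NumericMatrix logf, NumericMatrix logdur,
                NumericVector logpi, bool want_gamma = false) {
  const int T = logf.nrow();
  const int D = logdur.nrow();
  if (T == 0) stop("empty observation sequence");

  // cumulative emission log-likelihoods per state, E[t][j] = sum_{u<=t}
  std::vector<std::vector<double>> E(T + 1, std::vector<double>(2, 0.0));
  for (int t = 1; t <= T; ++t)
    for (int j = 0; j < 2; ++j)
      E[t][j] = E[t - 1][j] + logf(t - 1, j);

  // forward: alpha[t][j] = log P(obs 1..t, segment of state j ends at t)
  std::vector<std::vector<double>> alpha(T + 1,
      std::vector<double>(2, R_NegInf));
  std::vector<double> buf;
  buf.reserve(D);
  for (int t = 1; t <= T; ++t) {
    for (int j = 0; j < 2; ++j) {
      buf.clear();
      int dmax = std::min(D, t);
      for (int d = 1; d <= dmax; ++d) {
        double prev = (t - d == 0) ? logpi[j] : alpha[t - d][1 - j];
        if (!R_FINITE(prev)) continue;
        buf.push_back(prev + logdur(d - 1, j) + (E[t][j] - E[t - d][j]));
      }
      alpha[t][j] = buf.empty() ? R_NegInf : logsumexp(buf);
    }
  }
  std::vector<double> fin = {alpha[T][0], alpha[T][1]};
  double loglik = logsumexp(fin);
  if (!R_FINITE(loglik)) stop("HSMM likelihood underflow");

  // backward: beta[t][j] = log P(obs t+1..T | j-segment ended at t)
  std::vector<std::vector<double>> beta(T + 1,
      std::vector<double>(2, R_NegInf));
  beta[T][0] = beta[T][1] = 0.0;
  for (int t = T - 1; t >= 0; --t) {
    for (int j = 0; j < 2; ++j) {
      int j2 = 1 - j;
      buf.clear();
      int dmax = std::min(D, T - t);
      for (int d = 1; d <= dmax; ++d) {
        double nxt = beta[t + d][j2];
        if (!R_FINITE(nxt)) continue;
        buf.push_back(logdur(d - 1, j2) + (E[t + d][j2] - E[t][j2]) + nxt);
      }
      beta[t][j] = buf.empty() ? R_NegInf : logsumexp(buf);
    }
  }
  // beta at t=0 conditions on "next state is j", i.e. uses logdur of j
  for (int j = 0; j < 2; ++j) {
    buf.clear();
    int dmax = std::min(D, T);
    for (int d = 1; d <= dmax; ++d) {
      double nxt = beta[d][j];
      if (!R_FINITE(nxt)) continue;
      buf.push_back(logdur(d - 1, j) + (E[d][j] - E[0][j]) + nxt);
    }
    // (kept for clarity; initial-state stats come from eta below)
  }

  // segment posteriors eta(t, d, j) accumulated into sufficient stats
  std::vector<std::vector<double>> occ_diff(T + 2,
      std::vector<double>(2, 0.0));
  double durN[2] = {0, 0}, durS[2] = {0, 0}, durS2[2] = {0, 0};
  double pi_new[2] = {0, 0};
  for (int t = 1; t <= T; ++t) {
    for (int j = 0; j < 2; ++j) {
      if (!R_FINITE(beta[t][j])) continue;
      int dmax = std::min(D, t);
      for (int d = 1; d <= dmax; ++d) {
        double prev = (t - d == 0) ? logpi[j] : alpha[t - d][1 - j];
        if (!R_FINITE(prev)) continue;
        double le = prev + logdur(d - 1, j) + (E[t][j] - E[t - d][j]) +
                    beta[t][j] - loglik;
        double eta = std::exp(le);
        if (eta <= 0) continue;
        occ_diff[t - d + 1][j] += eta;
        occ_diff[t + 1][j] -= eta;
        durN[j] += eta;
        durS[j] += eta * d;
        durS2[j] += eta * (double)d * (double)d;
        if (t - d == 0) pi_new[j] += eta;
      }
    }
  }
  // occupancy gamma[t][j] by prefix sum; emission sufficient stats
  NumericMatrix gamma_out(want_gamma ? T : 0, 2);
  double run[2] = {0, 0};
  double wsum[2] = {0, 0}, gsum[2] = {0, 0};
  for (int t = 1; t <= T; ++t) {
    for (int j = 0; j < 2; ++j) {
      run[j] += occ_diff[t][j];
      gsum[j] += run[j];
      wsum[j] += run[j] * x[t - 1];
      if (want_gamma) gamma_out(t - 1, j) = run[j];
    }
  }
  return List::create(
    _["loglik"] = loglik,
    _["emis_wsum"] = NumericVector::create(wsum[0], wsum[1]),
    _["emis_gsum"] = NumericVector::create(gsum[0], gsum[1]),
    _["dur_n"] = NumericVector::create(durN[0], durN[1]),
    _["dur_sum"] = NumericVector::create(durS[0], durS[1]),
    _["dur_sum2"] = NumericVector::create(durS2[0], durS2[1]),
    _["pi_new"] = NumericVector::create(pi_new[0], pi_new[1]),
    _["gamma"] = gamma_out);
}

// Viterbi decoding under the same segment likelihood.  Returns the
// state (1 = foreground, 2 = background) of every observation.  Ties
// at the final-state choice resolve toward background.
// [[Rcpp::export(name = ".hsmm_viterbi")]]
IntegerVector hsmm_viterbi(NumericMatrix logf, NumericMatrix logdur,
                           NumericVector logpi) {
  const int T = logf.nrow();
  const int D = logdur.nrow();
  std::vector<std::vector<double>> E(T + 1, std::vector<double>(2, 0.0));
  for (int t = 1; t <= T; ++t)
    for (int j = 0; j < 2; ++j)
      E[t][j] = E[t - 1][j] + logf(t - 1, j);

  std::vector<std::vector<double>> V(T + 1,
      std::vector<double>(2, R_NegInf));
  std::vector<std::vector<int>> bestd(T + 1, std::vector<int>(2, 0));
  for (int t = 1; t <= T; ++t) {
    for (int j = 0; j < 2; ++j) {
      double best = R_NegInf;
      int barg = 0;
      int dmax = std::min(D, t);
      for (int d = 1; d <= dmax; ++d) {
        double prev = (t - d == 0) ? logpi[j] : V[t - d][1 - j];
        if (!R_FINITE(prev)) continue;
        double v = prev + logdur(d - 1, j) + (E[t][j] - E[t - d][j]);
        if (v > best) { best = v; barg = d; }
      }
      V[t][j] = best;
      bestd[t][j] = barg;
    }
  }
  // final state: background (index 1) wins ties
  int j = (V[T][0] > V[T][1]) ? 0 : 1;
  IntegerVector path(T);
  int t = T;
  while (t > 0) {
    int d = bestd[t][j];
    if (d <= 0) stop("Viterbi backtrack failed");
    for (int u = t - d; u < t; ++u) path[u] = j + 1;
    t -= d;
    j = 1 - j;
  }
  return path;
}

// All within-chromosome pairwise distances <= maxdist for a sorted
// position vector (two-pointer sweep).
// [[Rcpp::export(name = ".pair_distances_sorted")]]
NumericVector pair_distances_sorted(NumericVector pos, double maxdist) {
  const int n = pos.size();
  std::vector<double> out;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = pos[j] - pos[i];
      if (d > maxdist) break;
      out.push_back(d);
    }
  }
  return NumericVector(out.begin(), out.end());
}
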