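// Discrete-emission HMM core: scaled forward-backward (Baum-Welch),
// Viterbi decoding and forward log-likelihood.  States and symbols are
// 0-based here; the R layer owns labels and ordering conventions.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double emit_at(const NumericMatrix& emit, int i, int o) {
  double b = emit(i, o);
  return b > 1e-300 ? b : 1e-300;  // floor only for evaluation, not updates
}

// [[Rcpp::export]]
double cpp_forward_loglik(const IntegerVector& obs,
                          const NumericVector& start,
                          const NumericMatrix& trans,
                          const NumericMatrix& emit) {
  const int N = start.size(), T = obs.size();
  std::vector<double> a(N), a2(N);
  double ll = 0.0;
  double c = 0.0;
  for (int i = 0; i < N; ++i) { a[i] = start[i] * emit_at(emit, i, obs[0]); c += a[i]; }
  ll += std::log(c);
  for (int i = 0; i < N; ++i) a[i] /= c;
  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int j = 0; j < N; ++j) {
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += a[i] * trans(i, j);
      a2[j] = s * emit_at(emit, j, obs[t]);
      c += a2[j];
    }
    ll += std::log(c);
    for (int j = 0; j < N; ++j) a[j] = a2[j] / c;
  }
  return ll;
}

// [[Rcpp::export]]
IntegerVector cpp_viterbi(const IntegerVector& obs,
                          const NumericVector& start,
                          const NumericMatrix& trans,
                          const NumericMatrix& emit) {
  const int N = start.size(), T = obs.size();
  NumericMatrix delta(T, N);
  IntegerMatrix psi(T, N);
  for (int i = 0; i < N; ++i)
    delta(0, i) = std::log(start[i]) + std::log(emit_at(emit, i, obs[0]));
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < N; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < N; ++i) {
        double v = delta(t - 1, i) + std::log(trans(i, j));
        if (v > best) { best = v; arg = i; }  // strict >: ties -> lower index
      }
      delta(t, j) = best + std::log(emit_at(emit, j, obs[t]));
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  for (int i = 0; i < N; ++i)
    if (delta(T - 1, i) > best) { best = delta(T - 1, i); path[T - 1] = i; }
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}

// [[Rcpp::export]]
List cpp_baum_welch(const List& sequences,
                    NumericVector start, NumericMatrix trans,
                    NumericMatrix emit, double tol, int maxiter) {
  const int N = start.size(), M = emit.ncol();
  const int S = sequences.size();
  std::vector<IntegerVector> seqs(S);
  for (int s = 0; s < S; ++s) seqs[s] = sequences[s];
  std::vector<double> ll_trace;
  double prev_ll = R_NegInf;
  NumericVector st = clone(start);
  NumericMatrix tr = clone(trans), em = clone(emit);
  int iter = 0;
  for (iter = 0; iter < maxiter; ++iter) {
    double total_ll = 0.0;
    NumericVector acc_start(N);
    NumericMatrix acc_xi(N, N), acc_gamma_o(N, M);
    NumericVector acc_gamma_t(N);  // gamma summed over t < T-1 (trans denom)
    for (int s = 0; s < S; ++s) {
      const IntegerVector& obs = seqs[s];
      const int T = obs.size();
      NumericMatrix alpha(T, N), beta(T, N);
      NumericVector c(T);
      // scaled forward
      double cs = 0.0;
      for (int i = 0; i < N; ++i) {
        alpha(0, i) = st[i] * emit_at(em, i, obs[0]);
        cs += alpha(0, i);
      }
      c[0] = cs;
      for (int i = 0; i < N; ++i) alpha(0, i) /= cs;
      for (int t = 1; t < T; ++t) {
        cs = 0.0;
        for (int j = 0; j < N; ++j) {
          double v = 0.0;
          for (int i = 0; i < N; ++i) v += alpha(t - 1, i) * tr(i, j);
          alpha(t, j) = v * emit_at(em, j, obs[t]);
          cs += alpha(t, j);
        }
        c[t] = cs;
        for (int j = 0; j < N; ++j) alpha(t, j) /= cs;
      }
      for (int t = 0; t < T; ++t) total_ll += std::log(c[t]);
      // scaled backward
      for (int i = 0; i < N; ++i) beta(T - 1, i) = 1.0;
      for (int t = T - 2; t >= 0; --t) {
        for (int i = 0; i < N; ++i) {
          double v = 0.0;
          for (int j = 0; j < N; ++j)
            v += tr(i, j) * emit_at(em, j, obs[t + 1]) * beta(t + 1, j);
          beta(t, i) = v / c[t + 1];
        }
      }
      // accumulate gamma and xi
      for (int t = 0; t < T; ++t) {
        double gsum = 0.0;
        std::vector<double> g(N);
        for (int i = 0; i < N; ++i) { g[i] = alpha(t, i) * beta(t, i); gsum += g[i]; }
        for (int i = 0; i < N; ++i) {
          double gi = g[i] / gsum;
          acc_gamma_o(i, obs[t]) += gi;
          if (t == 0) acc_start[i] += gi;
          if (t < T - 1) acc_gamma_t[i] += gi;
        }
      }
      for (int t = 0; t < T - 1; ++t) {
        for (int i = 0; i < N; ++i) {
          double ai = alpha(t, i);
          if (ai == 0.0) continue;
          for (int j = 0; j < N; ++j)
            acc_xi(i, j) += ai * tr(i, j) * emit_at(em, j, obs[t + 1]) *
                            beta(t + 1, j) / c[t + 1];
        }
      }
    }
    ll_trace.push_back(total_ll);
    // M step
    double ssum = 0.0;
    for (int i = 0; i < N; ++i) ssum += acc_start[i];
    for (int i = 0; i < N; ++i) st[i] = acc_start[i] / ssum;
    for (int i = 0; i < N; ++i) {
      if (acc_gamma_t[i] > 0) {
        double rs = 0.0;
        for (int j = 0; j < N; ++j) rs += acc_xi(i, j);
        if (rs > 0) for (int j = 0; j < N; ++j) tr(i, j) = acc_xi(i, j) / rs;
      }
      double gs = 0.0;
      for (int m = 0; m < M; ++m) gs += acc_gamma_o(i, m);
      if (gs > 0) for (int m = 0; m < M; ++m) em(i, m) = acc_gamma_o(i, m) / gs;
    }
    if (iter > 0 &&
        std::fabs(total_ll - prev_ll) < tol * std::fabs(prev_ll)) {
      prev_ll = total_ll;
      ++iter;
      break;
    }
    prev_ll = total_ll;
  }
  return List::create(_["start"] = st, _["trans"] = tr, _["emit"] = em,
                      _["loglik"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["iterations"] = iter);
}
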