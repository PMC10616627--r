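#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Cholesky of a small symmetric positive definite matrix (row-major,
// k x k). Returns false when the matrix is not numerically PD.
static bool chol_small(const double* A, int k, double* L) {
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * k + j];
      for (int p = 0; p < j; ++p) s -= L[i * k + p] * L[j * k + p];
      if (i == j) {
        if (s <= 1e-12) return false;
        L[i * k + i] = std::sqrt(s);
      } else {
        L[i * k + j] = s / L[j * k + j];
      }
    }
  }
  return true;
}

// Solve L w = u (forward substitution) and return w'w = u' (LL')^{-1} u.
static double quad_from_chol(const double* L, const double* u, int k,
                             double* w) {
  double q = 0.0;
  for (int i = 0; i < k; ++i) {
    double s = u[i];
    for (int p = 0; p < i; ++p) s -= L[i * k + p] * w[p];
    w[i] = s / L[i * k + i];
    q += w[i] * w[i];
  }
  return q;
}

// Exhaustive enumeration of causal configurations of size 1..k_max over
// a candidate set, accumulating per-variant posterior inclusion mass.
//
// Summary-statistic Bayes factor of configuration c against the null:
// z_c ~ N(0, R_cc + a R_cc R_cc) under the config model versus
// z_c ~ N(0, R_cc) under the null (a = n * prior_sd^2), which collapses
// to
//   log BF(c) = -1/2 log det(I + a R_cc) + (a/2) z_c' (I + a R_cc)^{-1} z_c
// and is well defined for any PSD R_cc. The posterior weight multiplies
// BF(c) by the product of the member priors and the size prior.
// Two passes keep the log-sum-exp stable without storing every
// configuration: pass 0 finds the maximum log weight, pass 1
// accumulates normalized mass per variant.
// Sizes below k_min are skipped (the caller may handle them itself over
// a larger variant set). Returns UNNORMALIZED accumulations: per-variant
// sums of exp(logw - max_logw), their total, and max_logw, so the caller
// can merge several enumerations before normalizing.
// [[Rcpp::export]]
List enumerate_config_bf(NumericMatrix R, NumericVector z, double a,
                         NumericVector log_prior,
                         NumericVector size_log_prior, int k_max,
                         int k_min = 1) {
  const int m = R.nrow();
  if (k_max > 8) stop("k_max above 8 is not supported");

  std::vector<int> idx(k_max);
  double A[64], L[64], zc[8], wbuf[8];

  NumericVector pip_num(m);
  double max_logw = R_NegInf, sumw = 0.0;

  for (int pass = 0; pass < 2; ++pass) {
    for (int k = (k_min < 1 ? 1 : k_min); k <= k_max && k <= m; ++k) {
      for (int i = 0; i < k; ++i) idx[i] = i;
      while (true) {
        for (int i = 0; i < k; ++i) {
          zc[i] = z[idx[i]];
          for (int j = 0; j < k; ++j) A[i * k + j] = a * R(idx[i], idx[j]);
          A[i * k + i] += 1.0;
        }
        double logw = R_NegInf;
        if (chol_small(A, k, L)) {
          double logdet = 0.0;
          for (int i = 0; i < k; ++i) logdet += 2.0 * std::log(L[i * k + i]);
          double quad = quad_from_chol(L, zc, k, wbuf);
          double lpri = size_log_prior[k - 1];
          for (int i = 0; i < k; ++i) lpri += log_prior[idx[i]];
          logw = -0.5 * logdet + 0.5 * a * quad + lpri;
        }
        if (pass == 0) {
          if (logw > max_logw) max_logw = logw;
        } else if (logw > R_NegInf) {
          double w = std::exp(logw - max_logw);
          sumw += w;
          for (int i = 0; i < k; ++i) pip_num[idx[i]] += w;
        }
        int pos = k - 1;
        while (pos >= 0 && idx[pos] == m - k + pos) --pos;
        if (pos < 0) break;
        ++idx[pos];
        for (int i = pos + 1; i < k; ++i) idx[i] = idx[i - 1] + 1;
      }
    }
  }
  return List::create(_["pip_num"] = pip_num, _["sum_w"] = sumw,
                      _["max_logw"] = max_logw);
}
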