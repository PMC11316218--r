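#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// P(t) = U diag(exp(lambda * t)) W for a reversible rate matrix whose
// symmetrized eigendecomposition (U, lambda, W) is precomputed in R.
static void prob_matrix(const NumericMatrix& U, const NumericVector& lambda,
                        const NumericMatrix& W, double t, double* P) {
  const int n = 20;
  double el[20];
  for (int k = 0; k < n; ++k) el[k] = std::exp(lambda[k] * t);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < n; ++k) s += U(i, k) * el[k] * W(k, j);
      P[i * n + j] = s;
    }
  }
}

// log-likelihood of divergence time t for a 20x20 matrix of aligned
// residue-pair counts N: sum_ab N_ab log(pi_a P_ab(t)).
static double loglik(const NumericMatrix& N, const NumericMatrix& U,
                     const NumericVector& lambda, const NumericMatrix& W,
                     const NumericVector& pi, double t) {
  double P[400];
  prob_matrix(U, lambda, W, t, P);
  double ll = 0.0;
  for (int a = 0; a < 20; ++a) {
    for (int b = 0; b < 20; ++b) {
      double n_ab = N(a, b);
      if (n_ab > 0.0) {
        double p = pi[a] * P[a * 20 + b];
        if (p < 1e-300) p = 1e-300;
        ll += n_ab * std::log(p);
      }
    }
  }
  return ll;
}

// golden-section maximization of the pair log-likelihood over [lo, cap]
static double optimize_t(const NumericMatrix& N, const NumericMatrix& U,
                         const NumericVector& lambda, const NumericMatrix& W,
                         const NumericVector& pi, double cap) {
  const double gr = 0.6180339887498949;
  double a = 1e-9, b = cap;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = loglik(N, U, lambda, W, pi, x1);
  double f2 = loglik(N, U, lambda, W, pi, x2);
  for (int it = 0; it < 80 && (b - a) > 1e-9; ++it) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = loglik(N, U, lambda, W, pi, x2);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = loglik(N, U, lambda, W, pi, x1);
    }
  }
  return (a + b) / 2.0;
}

// [[Rcpp::export]]
List jtt_pair_mle_cpp(NumericMatrix N, NumericMatrix U, NumericVector lambda,
                      NumericMatrix W, NumericVector pi, double cap) {
  double ndiff = 0.0, ntot = 0.0;
  for (int a = 0; a < 20; ++a)
    for (int b = 0; b < 20; ++b) {
      ntot += N(a, b);
      if (a != b) ndiff += N(a, b);
    }
  if (ntot <= 0.0) stop("no shared gap-free columns");
  if (ndiff == 0.0)
    return List::create(_["distance"] = 0.0, _["saturated"] = false);
  double t = optimize_t(N, U, lambda, W, pi, cap);
  bool sat = t >= cap - 1e-6;
  if (sat) t = cap;
  return List::create(_["distance"] = t, _["saturated"] = sat);
}

// enc: ntaxa x width integer matrix, residues 0..19, negative for gap/unknown
// [[Rcpp::export]]
List jtt_dist_matrix_cpp(IntegerMatrix enc, NumericMatrix U,
                         NumericVector lambda, NumericMatrix W,
                         NumericVector pi, double cap) {
  const int n = enc.nrow(), L = enc.ncol();
  NumericMatrix D(n, n);
  LogicalMatrix sat(n, n);
  IntegerMatrix shared(n, n);
  NumericMatrix N(20, 20);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      std::fill(N.begin(), N.end(), 0.0);
      int ns = 0, ndiff = 0;
      for (int c = 0; c < L; ++c) {
        int a = enc(i, c), b = enc(j, c);
        if (a >= 0 && b >= 0) {
          N(a, b) += 1.0;
          ++ns;
          if (a != b) ++ndiff;
        }
      }
      shared(i, j) = shared(j, i) = ns;
      if (ns == 0) {
        D(i, j) = D(j, i) = NA_REAL;
        continue;
      }
      double d;
      bool s = false;
      if (ndiff == 0) {
        d = 0.0;
      } else {
        d = optimize_t(N, U, lambda, W, pi, cap);
        s = d >= cap - 1e-6;
        if (s) d = cap;
      }
      D(i, j) = D(j, i) = d;
      sat(i, j) = sat(j, i) = s;
    }
  }
  return List::create(_["distance"] = D, _["saturated"] = sat,
                      _["shared"] = shared);
}
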