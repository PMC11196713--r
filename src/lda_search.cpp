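// Hot loop for the budgeted subset searches: leave-one-out
// cross-validated training accuracy and hold-out test accuracy of a
// Gaussian equal-covariance (LDA) classifier, for every predictor subset
// in a list. Leave-one-out refits reuse the full-sample scatter through a
// Sherman-Morrison rank-1 downdate, so each fold costs O(p^2) instead of
// a full refit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Discriminant scores under the equal-covariance Gaussian rule with
// empirical priors; ties break toward the smaller class index.
static int predict_class(const rowvec& x, const mat& M, const mat& A,
                         const vec& logprior, int K) {
  int best = 0;
  double best_s = -datum::inf;
  for (int g = 0; g < K; ++g) {
    double s = dot(x * A, M.row(g)) -
      0.5 * dot(M.row(g) * A, M.row(g)) + logprior(g);
    if (s > best_s) { best_s = s; best = g; }
  }
  return best;
}

// [[Rcpp::export]]
arma::mat cpp_lda_subset_search(const arma::mat& Xtr,
                                const arma::ivec& ytr,
                                const arma::mat& Xte,
                                const arma::ivec& yte,
                                const arma::imat& subsets,
                                int n_classes) {
  const int n = Xtr.n_rows;
  const int K = n_classes;
  const int m = subsets.n_rows;
  const int k = subsets.n_cols;
  const int nte = Xte.n_rows;
  mat out(m, 2);
  out.fill(datum::nan);

  vec ng(K, fill::zeros);
  for (int i = 0; i < n; ++i) ng(ytr(i) - 1) += 1.0;
  vec logprior_full = log(ng / n);
  vec logprior_loo(K);

  for (int s = 0; s < m; ++s) {
    uvec cols(k);
    for (int j = 0; j < k; ++j) cols(j) = subsets(s, j);
    mat Xs = Xtr.cols(cols);
    mat Xse = nte > 0 ? Xte.cols(cols) : mat(0, k);

    // class means and pooled scatter
    mat M(K, k, fill::zeros);
    for (int i = 0; i < n; ++i) M.row(ytr(i) - 1) += Xs.row(i);
    for (int g = 0; g < K; ++g) M.row(g) /= ng(g);
    mat S = Xs.t() * Xs;
    for (int g = 0; g < K; ++g) S -= ng(g) * (M.row(g).t() * M.row(g));

    mat Sinv;
    bool ok = inv_sympd(Sinv, S);
    if (!ok) continue;  // singular pooled scatter: leave NaN

    // hold-out test accuracy of the model fit on the full training set
    if (nte > 0) {
      mat A = (n - K) * Sinv;  // inverse pooled covariance (up to scale)
      int correct = 0;
      for (int i = 0; i < nte; ++i) {
        if (predict_class(Xse.row(i), M, A, logprior_full, K) ==
            yte(i) - 1) ++correct;
      }
      out(s, 1) = double(correct) / nte;
    }

    // leave-one-out on the training set
    int correct = 0;
    bool loo_ok = true;
    for (int i = 0; i < n && loo_ok; ++i) {
      int g = ytr(i) - 1;
      double cgi = ng(g) / (ng(g) - 1.0);
      rowvec u = Xs.row(i) - M.row(g);
      vec Su = Sinv * u.t();
      double denom = 1.0 - cgi * dot(u, Su);
      mat S2inv;
      if (denom > 1e-10) {
        S2inv = Sinv + cgi * (Su * Su.t()) / denom;
      } else {
        mat S2 = S - cgi * (u.t() * u);
        if (!inv_sympd(S2inv, S2)) { loo_ok = false; break; }
      }
      mat M2 = M;
      M2.row(g) = (ng(g) * M.row(g) - Xs.row(i)) / (ng(g) - 1.0);
      for (int h = 0; h < K; ++h) {
        logprior_loo(h) = std::log((ng(h) - (h == g ? 1.0 : 0.0)) /
                                   (n - 1.0));
      }
      mat A2 = (n - 1 - K) * S2inv;
      if (predict_class(Xs.row(i), M2, A2, logprior_loo, K) == g) ++correct;
    }
    if (loo_ok) out(s, 0) = double(correct) / n;
  }
  return out;
}
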