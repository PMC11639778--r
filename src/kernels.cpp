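// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// NCA objective and gradient for diagonal (per-feature) weights with a
// weighted city-block distance: D_w(i,j) = sum_r w_r^2 |x_ir - x_jr|.
// Objective: F(w) = (1/n) sum_i p_i - lambda * sum_r w_r^2, where
// p_i = sum_{j != i, y_j = y_i} p_ij and p_ij is the softmax of -D_w over
// j != i (shifted by the row minimum for numerical stability).
// [[Rcpp::export]]
List nca_objective_grad_cpp(const arma::mat& X, const arma::ivec& y,
                            const arma::vec& w, double lambda,
                            bool want_grad) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec w2 = w % w;
  arma::vec gacc(p, arma::fill::zeros);
  double F = 0.0;

  for (arma::uword i = 0; i < n; ++i) {
    arma::mat A = arma::abs(X.each_row() - X.row(i)); // n x p
    arma::vec d = A * w2;
    d(i) = arma::datum::inf;
    double m = d.min();
    arma::vec e = arma::exp(-(d - m));
    e(i) = 0.0;
    double Z = arma::accu(e);
    if (Z <= 0.0) continue; // fully degenerate row: contributes 0
    arma::vec prob = e / Z;
    arma::vec same = arma::conv_to<arma::vec>::from(y == y(i));
    same(i) = 0.0;
    double pi = arma::dot(prob, same);
    F += pi;
    if (want_grad) {
      arma::vec t1 = A.t() * prob;          // sum_l p_il A_ilr
      arma::vec t2 = A.t() * (prob % same); // sum_{j in class} p_ij A_ijr
      gacc += pi * t1 - t2;
    }
  }

  double value = F / n - lambda * arma::accu(w2);
  List out = List::create(_["value"] = value);
  if (want_grad) {
    arma::vec grad = (2.0 / n) * (w % gacc) - 2.0 * lambda * w;
    out["grad"] = grad;
  }
  return out;
}

static inline double dist_pair(const arma::rowvec& u, const arma::rowvec& v,
                               double nu, double nv, int metric) {
  if (metric == 0) return arma::accu(arma::abs(u - v));        // cityblock
  if (metric == 1) return std::sqrt(arma::accu(arma::square(u - v)));
  double c = 1.0 - arma::dot(u, v) / (nu * nv);                // cosine
  return c > 0.0 ? c : 0.0;
}

// Weighted kNN with hard rules needed by the ensemble:
//  - metric: 0 cityblock, 1 euclidean, 2 cosine (1 - cos similarity)
//  - wscheme: 0 equal, 1 inverse (1/d), 2 squared inverse (1/d^2)
//  - neighbor ties at the k-th distance: stable training order, exactly k kept
//  - zero-distance neighbors under inverse weights: majority among them
//  - score ties: smallest class index wins
// y is 1..n_classes; returns predictions in the same coding.
// When loo is true, testX must be trainX and row t is excluded from its own
// neighbor pool (leave-one-out prediction of the training set).
// [[Rcpp::export]]
arma::ivec knn_predict_cpp(const arma::mat& trainX, const arma::ivec& trainy,
                           const arma::mat& testX, int metric, int k,
                           int wscheme, int n_classes, bool loo = false) {
  const arma::uword n = trainX.n_rows, m = testX.n_rows;
  if ((arma::uword)k > (loo ? n - 1 : n))
    stop("k exceeds the number of training samples");
  arma::vec ntr(n, arma::fill::ones), nte(m, arma::fill::ones);
  if (metric == 2) {
    for (arma::uword i = 0; i < n; ++i) ntr(i) = arma::norm(trainX.row(i), 2);
    for (arma::uword i = 0; i < m; ++i) nte(i) = arma::norm(testX.row(i), 2);
  }
  arma::ivec pred(m);
  std::vector<arma::uword> idx(n);
  arma::vec d(n);
  for (arma::uword t = 0; t < m; ++t) {
    for (arma::uword j = 0; j < n; ++j)
      d(j) = dist_pair(testX.row(t), trainX.row(j), nte(t), ntr(j), metric);
    if (loo) d(t) = arma::datum::inf;
    for (arma::uword j = 0; j < n; ++j) idx[j] = j;
    std::stable_sort(idx.begin(), idx.end(),
                     [&](arma::uword a, arma::uword b) { return d(a) < d(b); });
    std::vector<double> score(n_classes, 0.0);
    bool zero_hit = false;
    if (wscheme != 0) {
      std::vector<int> zcount(n_classes, 0);
      for (int j = 0; j < k; ++j)
        if (d(idx[j]) == 0.0) { zero_hit = true; zcount[trainy(idx[j]) - 1]++; }
      if (zero_hit)
        for (int c = 0; c < n_classes; ++c) score[c] = zcount[c];
    }
    if (!zero_hit) {
      for (int j = 0; j < k; ++j) {
        double dd = d(idx[j]);
        double wt = 1.0;
        if (wscheme == 1) wt = 1.0 / dd;
        else if (wscheme == 2) wt = 1.0 / (dd * dd);
        score[trainy(idx[j]) - 1] += wt;
      }
    }
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (score[c] > score[best]) best = c;
    pred(t) = best + 1;
  }
  return pred;
}
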