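// Full-batch RMSprop on the RMSE loss, linear in the output weights.
// The random initial weights are drawn in R; this kernel is deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".rmsprop_cpp")]]
List rmsprop_cpp(const arma::mat& G, const arma::vec& y, const arma::vec& w0,
                 const double lr, const double rho, const double eps,
                 const int epochs) {
  const double n = static_cast<double>(G.n_rows);
  arma::vec w = w0;
  arma::vec v(w.n_elem, arma::fill::zeros);
  arma::vec r = G * w - y;
  double L = std::sqrt(arma::dot(r, r) / n);
  double initialLoss = L;
  arma::vec bestW = w;
  double bestLoss = L;
  int bestEpoch = 0;
  NumericVector losses(epochs);
  for (int t = 1; t <= epochs; ++t) {
    if (!std::isfinite(L)) {
      return List::create(_["diverged"] = true, _["epoch"] = t);
    }
    arma::vec g(w.n_elem, arma::fill::zeros);
    if (L > 0) g = (G.t() * r) / (n * L);
    v = rho * v + (1.0 - rho) * arma::square(g);
    w -= lr * g / (arma::sqrt(v) + eps);
    r = G * w - y;
    L = std::sqrt(arma::dot(r, r) / n);
    losses[t - 1] = L;
    if (std::isfinite(L) && L < bestLoss) {
      bestLoss = L;
      bestW = w;
      bestEpoch = t;
    }
  }
  if (!std::isfinite(L)) {
    return List::create(_["diverged"] = true, _["epoch"] = epochs);
  }
  return List::create(_["diverged"] = false,
                      _["weights"] = bestW,
                      _["loss"] = losses,
                      _["initialLoss"] = initialLoss,
                      _["bestEpoch"] = bestEpoch);
}

// k-means++ seeding with pre-drawn uniforms (one per center, from R's RNG):
// the first center is floor(u*n); each later center is drawn with
// probability proportional to the squared distance to the nearest chosen
// center, by inverse-CDF over the cumulative weights.
// [[Rcpp::export(name = ".kmeanspp_cpp")]]
arma::mat kmeanspp_cpp(const arma::mat& X, const int k,
                       const arma::vec& u) {
  const arma::uword n = X.n_rows;
  arma::mat centers(k, X.n_cols);
  arma::uword first = std::min<arma::uword>(
      static_cast<arma::uword>(u[0] * n), n - 1);
  centers.row(0) = X.row(first);
  if (k == 1) return centers;
  arma::vec xsq = arma::sum(arma::square(X), 1);
  arma::vec d2 = xsq + arma::dot(centers.row(0), centers.row(0))
      - 2.0 * X * centers.row(0).t();
  d2.elem(arma::find(d2 < 0)).zeros();
  for (int j = 1; j < k; ++j) {
    double total = arma::accu(d2);
    arma::uword pick;
    if (total <= 0) {
      pick = std::min<arma::uword>(static_cast<arma::uword>(u[j] * n), n - 1);
    } else {
      double threshold = u[j] * total;
      double cum = 0.0;
      pick = n - 1;
      for (arma::uword i = 0; i < n; ++i) {
        cum += d2[i];
        if (cum >= threshold) { pick = i; break; }
      }
    }
    centers.row(j) = X.row(pick);
    arma::vec dn = xsq + arma::dot(centers.row(j), centers.row(j))
        - 2.0 * X * centers.row(j).t();
    dn.elem(arma::find(dn < 0)).zeros();
    d2 = arma::min(d2, dn);
  }
  return centers;
}
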