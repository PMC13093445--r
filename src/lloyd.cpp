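// Lloyd iterations for K-means center initialization.
// Seeding (k-means++) and the restart protocol live in R so that all
// randomness flows through R's RNG; this kernel is fully deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Squared distances of every row of X to every row of C (n x k).
static arma::mat dist2(const arma::mat& X, const arma::mat& C,
                       const arma::vec& xsq) {
  arma::vec csq = arma::sum(arma::square(C), 1);
  arma::mat d = -2.0 * X * C.t();
  d.each_col() += xsq;
  d.each_row() += csq.t();
  d.elem(arma::find(d < 0)).zeros();
  return d;
}

// [[Rcpp::export(name = ".lloyd_cpp")]]
List lloyd_cpp(const arma::mat& X, const arma::mat& init,
               const int maxIter, const double tol) {
  const arma::uword k = init.n_rows;
  arma::mat centroids = init;
  arma::vec xsq = arma::sum(arma::square(X), 1);
  arma::uvec assign;
  std::vector<double> trace;
  int iter = 0;
  for (iter = 1; iter <= maxIter; ++iter) {
    arma::mat d2 = dist2(X, centroids, xsq);
    assign = arma::index_min(d2, 1);        // first minimum per row
    arma::vec mins = arma::min(d2, 1);
    trace.push_back(arma::accu(mins));
    arma::mat newC(k, X.n_cols, arma::fill::zeros);
    for (arma::uword j = 0; j < k; ++j) {
      arma::uvec members = arma::find(assign == j);
      if (members.n_elem > 0) {
        newC.row(j) = arma::mean(X.rows(members), 0);
      } else {
        // empty cluster: promote the point farthest from its centroid
        arma::uword far = mins.index_max();
        newC.row(j) = X.row(far);
        assign[far] = j;
        mins[far] = 0.0;
      }
    }
    double movement = std::sqrt(arma::accu(arma::square(newC - centroids)));
    centroids = newC;
    if (movement < tol) break;
  }
  // final assignment and inertia under the converged centroids
  arma::mat d2 = dist2(X, centroids, xsq);
  assign = arma::index_min(d2, 1);
  double J = arma::accu(arma::min(d2, 1));
  trace.push_back(J);
  IntegerVector assignOut(assign.n_elem);
  for (arma::uword i = 0; i < assign.n_elem; ++i) {
    assignOut[i] = static_cast<int>(assign[i]) + 1;  // 1-based for R
  }
  return List::create(_["centroids"] = centroids,
                      _["assignments"] = assignOut,
                      _["inertia"] = J,
                      _["nIter"] = std::min(iter, maxIter),
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
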