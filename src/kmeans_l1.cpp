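// L1 (Manhattan) k-means core: nearest-centroid assignment with
// lowest-index tie-breaking, component-wise median updates, empty-cluster
// reseeding to the instance farthest from its assigned centroid.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void assign_l1(const mat& X, const mat& cent, uvec& lab, vec& dmin,
                      double& obj) {
  const uword n = X.n_rows, k = cent.n_rows;
  obj = 0.0;
  for (uword i = 0; i < n; ++i) {
    double best = datum::inf;
    uword bj = 0;
    for (uword j = 0; j < k; ++j) {
      double d = accu(abs(X.row(i) - cent.row(j)));
      if (d < best) {  // strict: ties keep the lowest index
        best = d;
        bj = j;
      }
    }
    lab(i) = bj;
    dmin(i) = best;
    obj += best;
  }
}

// [[Rcpp::export]]
Rcpp::List kmeans_l1_fit(const arma::mat& X, arma::mat cent, int max_iter,
                         bool single_pass) {
  const uword n = X.n_rows, k = cent.n_rows;
  uvec lab(n, fill::zeros), prev(n);
  prev.fill(k + 1);
  vec dmin(n);
  std::vector<double> trace;
  double obj = 0.0;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    assign_l1(X, cent, lab, dmin, obj);
    trace.push_back(obj);
    if (single_pass) break;
    for (uword j = 0; j < k; ++j) {
      if (!any(lab == j)) {
        uword far = dmin.index_max();
        cent.row(j) = X.row(far);
        lab(far) = j;
        dmin(far) = 0.0;
      }
    }
    if (all(lab == prev)) break;
    prev = lab;
    for (uword j = 0; j < k; ++j) {
      uvec idx = find(lab == j);
      if (idx.n_elem > 0) cent.row(j) = median(X.rows(idx), 0);
    }
  }
  // make labels/objective consistent with the final centroids
  assign_l1(X, cent, lab, dmin, obj);
  trace.push_back(obj);
  return Rcpp::List::create(
      Rcpp::Named("centroids") = cent,
      Rcpp::Named("labels") = Rcpp::IntegerVector(lab.begin(), lab.end()),
      Rcpp::Named("objective") = obj,
      Rcpp::Named("objective_trace") = trace,
      Rcpp::Named("iterations") = (int)trace.size());
}
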