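#include <Rcpp.h>
using namespace Rcpp;

// Per-node gradient/hessian/count histogram: one pass over the node's
// samples per feature, bin index as accumulator address.
// [[Rcpp::export(name = ".hist_accumulate_cpp")]]
List hist_accumulate_cpp(IntegerMatrix binned, IntegerVector idx,
                         NumericVector grad, NumericVector hess, int mb) {
  int d = binned.ncol(), n = idx.size();
  NumericMatrix G(mb, d), H(mb, d), C(mb, d);
  for (int j = 0; j < d; ++j) {
    for (int t = 0; t < n; ++t) {
      int i = idx[t] - 1;
      int b = binned(i, j) - 1;
      G(b, j) += grad[i];
      H(b, j) += hess[i];
      C(b, j) += 1.0;
    }
  }
  return List::create(_["grad"] = G, _["hess"] = H, _["count"] = C);
}

// Evaluate one tree (node table in column vectors) on a feature matrix.
// [[Rcpp::export(name = ".tree_predict_cpp")]]
NumericVector tree_predict_cpp(LogicalVector is_leaf, IntegerVector feature,
                               NumericVector threshold, NumericVector weight,
                               IntegerVector left, IntegerVector right,
                               NumericMatrix features) {
  int n = features.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (!is_leaf[node]) {
      double x = features(i, feature[node] - 1);
      node = (x <= threshold[node] ? left[node] : right[node]) - 1;
    }
    out[i] = weight[node];
  }
  return out;
}
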