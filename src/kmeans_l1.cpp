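// k-means under the L1 (Manhattan) metric: assignment by minimum cityblock
// distance with lowest-index tie-break, centroid update by component-wise
// median, best of several random initialisations by total L1 inertia.
// All randomness (initial centroid rows) is supplied by the caller so runs
// are reproducible under R's RNG.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double l1_dist(const mat& X, int row, const mat& C, int crow) {
  double d = 0.0;
  for (uword f = 0; f < X.n_cols; ++f) d += std::abs(X(row, f) - C(crow, f));
  return d;
}

// assignment pass: labels (0-based) and distance to the winning centroid
static void assign_pass(const mat& X, const mat& C, ivec& labels, vec& dist) {
  const int n = X.n_rows, k = C.n_rows;
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bestd = l1_dist(X, i, C, 0);
    for (int c = 1; c < k; ++c) {
      double d = l1_dist(X, i, C, c);
      if (d < bestd) { bestd = d; best = c; }  // strict: ties keep lower index
    }
    labels(i) = best;
    dist(i) = bestd;
  }
}

static double col_median(std::vector<double>& v) {
  size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// [[Rcpp::export]]
Rcpp::List cpp_kmeans_l1(const arma::mat& X, int k,
                         const arma::imat& init_idx, int maxit = 100) {
  const int n = X.n_rows;
  const int n_rep = init_idx.n_rows;

  mat best_C;
  ivec best_labels(n);
  double best_inertia = datum::inf;
  vec rep_inertia(n_rep);

  for (int rep = 0; rep < n_rep; ++rep) {
    mat C(k, X.n_cols);
    for (int c = 0; c < k; ++c) C.row(c) = X.row(init_idx(rep, c));
    ivec labels(n, fill::value(-1)), old_labels(n);
    vec dist(n);

    for (int it = 0; it < maxit; ++it) {
      old_labels = labels;
      assign_pass(X, C, labels, dist);

      // empty cluster: re-seed at the point farthest from its centroid
      for (int c = 0; c < k; ++c) {
        if (!any(labels == c)) {
          uword far = dist.index_max();
          C.row(c) = X.row(far);
          assign_pass(X, C, labels, dist);
        }
      }
      if (all(labels == old_labels)) break;

      for (int c = 0; c < k; ++c) {
        uvec members = find(labels == c);
        for (uword f = 0; f < X.n_cols; ++f) {
          std::vector<double> v(members.n_elem);
          for (uword m = 0; m < members.n_elem; ++m) v[m] = X(members(m), f);
          C(c, f) = col_median(v);
        }
      }
    }
    assign_pass(X, C, labels, dist);
    double inertia = sum(dist);
    rep_inertia(rep) = inertia;
    if (inertia < best_inertia) {
      best_inertia = inertia;
      best_C = C;
      best_labels = labels;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("centroids") = best_C,
    Rcpp::Named("labels") = best_labels + 1,
    Rcpp::Named("inertia") = best_inertia,
    Rcpp::Named("replicate_inertia") = rep_inertia);
}

// [[Rcpp::export]]
Rcpp::List cpp_assign_l1(const arma::mat& X, const arma::mat& C) {
  ivec labels(X.n_rows);
  vec dist(X.n_rows);
  assign_pass(X, C, labels, dist);
  return Rcpp::List::create(Rcpp::Named("labels") = labels + 1,
                            Rcpp::Named("dist") = dist);
}
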