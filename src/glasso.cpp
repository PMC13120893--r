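// Graphical lasso: L1-penalised sparse inverse-covariance estimation by
// block coordinate descent on the working covariance (Friedman-style).
// The penalty applies to off-diagonal precision entries only.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double soft_threshold(double x, double lam) {
  if (x > lam) return x - lam;
  if (x < -lam) return x + lam;
  return 0.0;
}

// [[Rcpp::export]]
arma::mat cpp_glasso(const arma::mat& S, double lambda,
                     double tol = 1e-7, int maxit = 1000) {
  const int p = S.n_rows;
  if (p == 1) {
    mat theta(1, 1);
    theta(0, 0) = 1.0 / S(0, 0);
    return theta;
  }

  mat W = S;                 // working covariance; diagonal unpenalised
  mat B(p - 1, p, fill::zeros);  // per-column lasso coefficients

  const double inner_tol = tol / 10.0;
  const int inner_maxit = 10000;
  bool converged = false;

  for (int it = 0; it < maxit; ++it) {
    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      // partition indices: all but j
      uvec idx(p - 1);
      for (int a = 0, b = 0; a < p; ++a) if (a != j) idx(b++) = a;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = B.col(j);

      // lasso: min 1/2 b' W11 b - s12' b + lambda ||b||_1
      for (int ii = 0; ii < inner_maxit; ++ii) {
        double delta = 0.0;
        for (int l = 0; l < p - 1; ++l) {
          double r = s12(l) - dot(W11.row(l).t(), beta) + W11(l, l) * beta(l);
          double bnew = soft_threshold(r, lambda) / W11(l, l);
          double d = std::abs(bnew - beta(l));
          if (d > delta) delta = d;
          beta(l) = bnew;
        }
        if (delta < inner_tol) break;
      }
      B.col(j) = beta;
      vec w12 = W11 * beta;
      double ch = 0.0;
      for (int l = 0; l < p - 1; ++l) {
        double d = std::abs(W(idx(l), j) - w12(l));
        if (d > ch) ch = d;
        W(idx(l), j) = w12(l);
        W(j, idx(l)) = w12(l);
      }
      if (ch > max_change) max_change = ch;
    }
    if (max_change < tol) { converged = true; break; }
  }
  if (!converged)
    Rcpp::stop("graphical lasso failed to converge in %d iterations", maxit);

  // recover the precision matrix from (W, B)
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx(p - 1);
    for (int a = 0, b = 0; a < p; ++a) if (a != j) idx(b++) = a;
    vec beta = B.col(j);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double theta_jj = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = theta_jj;
    for (int l = 0; l < p - 1; ++l) Theta(idx(l), j) = -beta(l) * theta_jj;
  }
  return 0.5 * (Theta + Theta.t());
}
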