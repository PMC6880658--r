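// Coordinate-descent graphical lasso (Friedman-Hastie-Tibshirani scheme)
// over a decreasing penalty path with warm starts. Written for the small,
// dense problems of symptom networks (p ~ 10); the path is the unit of work
// because the permutation and bootstrap layers refit it thousands of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One glasso solve at penalty lambda. W and B are warm starts, updated in
// place. W approximates the estimated covariance, B holds the per-column
// lasso coefficients. Returns the number of outer sweeps used.
static int glasso_fit(const arma::mat &S, double lambda, arma::mat &W,
                      arma::mat &B, double thr, int maxit) {
  int p = S.n_rows;
  if (p == 1) return 0;
  double sbar = 0.0;
  for (int i = 0; i < p; i++)
    for (int j = 0; j < p; j++)
      if (i != j) sbar += std::fabs(S(i, j));
  sbar /= (p * (p - 1));
  double tol_outer = thr * std::max(sbar, 1e-12);
  double tol_inner = 0.1 * tol_outer;
  int it;
  arma::vec c(p);
  for (it = 0; it < maxit; it++) {
    double dmax = 0.0;
    for (int j = 0; j < p; j++) {
      // lasso for column j: minimize .5 b'W11 b - s12'b + lambda|b|_1
      // c caches W(k,·) %*% b so unchanged coordinates cost O(1)
      c.zeros();
      for (int m = 0; m < p; m++) {
        double bm = B(m, j);
        if (m == j || bm == 0.0) continue;
        for (int k = 0; k < p; k++) c(k) += W(k, m) * bm;
      }
      for (int inner = 0; inner < 100; inner++) {
        double dinner = 0.0;
        for (int k = 0; k < p; k++) {
          if (k == j) continue;
          double g = S(k, j) - (c(k) - W(k, k) * B(k, j));
          double bnew = soft(g, lambda) / W(k, k);
          double delta = bnew - B(k, j);
          if (delta != 0.0) {
            double d = std::fabs(delta);
            if (d > dinner) dinner = d;
            B(k, j) = bnew;
            for (int m = 0; m < p; m++) c(m) += W(m, k) * delta;
          }
        }
        if (dinner < tol_inner) break;
      }
      for (int k = 0; k < p; k++) {
        if (k == j) continue;
        double w = c(k);  // (W11 beta)_k, maintained incrementally above
        double d = std::fabs(w - W(k, j));
        if (d > dmax) dmax = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (dmax < tol_outer) break;
  }
  return it + 1;
}

// Recover the precision matrix from (W, B); entries are exactly zero where
// the lasso coefficients are zero (pattern symmetrized by OR).
static arma::mat precision_from(const arma::mat &W, const arma::mat &B) {
  int p = W.n_rows;
  arma::mat K(p, p, arma::fill::zeros);
  arma::vec kdiag(p);
  for (int j = 0; j < p; j++) {
    double q = W(j, j);
    for (int m = 0; m < p; m++)
      if (m != j) q -= W(m, j) * B(m, j);
    kdiag(j) = 1.0 / q;
  }
  for (int j = 0; j < p; j++) {
    K(j, j) = kdiag(j);
    for (int m = 0; m < p; m++) {
      if (m == j) continue;
      if (B(m, j) != 0.0 || B(j, m) != 0.0) {
        double a = -B(m, j) * kdiag(j);
        double b = -B(j, m) * kdiag(m);
        K(m, j) = 0.5 * (a + b);
      }
    }
  }
  return 0.5 * (K + K.t());
}

// Graphical-lasso path. S: correlation-scale input matrix; lambdas must be
// decreasing. Returns precision estimates, Gaussianized log-likelihood terms
// (log det K - tr(SK)), and edge counts per path point.
// [[Rcpp::export(name = ".glasso_path_cpp")]]
List glasso_path_cpp(arma::mat S, arma::vec lambdas,
                     bool penalize_diagonal = false, double thr = 1e-6,
                     int maxit = 1000) {
  int p = S.n_rows, nl = lambdas.n_elem;
  arma::cube Ks(p, p, nl);
  arma::vec loglik(nl), nedge(nl), sweeps(nl);
  arma::mat W = S, B(p, p, arma::fill::zeros);
  for (int l = 0; l < nl; l++) {
    double lambda = lambdas(l);
    W.diag() = S.diag();
    if (penalize_diagonal) W.diag() += lambda;
    int it = glasso_fit(S, lambda, W, B, thr, maxit);
    arma::mat K = precision_from(W, B);
    Ks.slice(l) = K;
    sweeps(l) = it;
    int e = 0;
    for (int i = 0; i < p; i++)
      for (int j = i + 1; j < p; j++)
        if (K(i, j) != 0.0) e++;
    nedge(l) = e;
    double ld, sign;
    bool ok = arma::log_det(ld, sign, K);
    if (!ok || sign <= 0.0) {
      loglik(l) = -arma::datum::inf;
    } else {
      loglik(l) = ld - arma::trace(S * K);
    }
  }
  return List::create(Named("precision") = Ks, Named("loglik_term") = loglik,
                      Named("n_edges") = nedge, Named("sweeps") = sweeps);
}
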