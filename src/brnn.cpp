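// Bayesian-regularized single-hidden-layer regression network.
//
// Model: yhat = b2 + sum_k v_k * tanh(b1_k + x' w_k), trained by minimizing
// F(w) = beta * ED + alpha * EW with ED = sum of squared residuals and
// EW = sum of squared weights. The weights are updated with
// Levenberg-Marquardt (Gauss-Newton with adaptive damping); after each
// accepted step the regularization hyper-parameters are re-estimated by the
// evidence approximation: gamma = p - 2*alpha*tr(H^-1),
// alpha = gamma / (2 EW), beta = (n - gamma) / (2 ED), H = 2*beta*J'J +
// 2*alpha*I. Inputs and targets are expected standardized by the caller.

#include <RcppArmadillo.h>

using namespace arma;

static vec forward(const mat& X, const mat& W1, const vec& b1,
                   const vec& v, double b2, mat& Z) {
  Z = X * W1.t();
  Z.each_row() += b1.t();
  Z = tanh(Z);
  return Z * v + b2;
}

// parameter packing: [vec(W1) column-major (h*d), b1 (h), v (h), b2]
static void unpack(const vec& w, int d, int h, mat& W1, vec& b1, vec& v,
                   double& b2) {
  W1 = reshape(w.subvec(0, h * d - 1), h, d);
  b1 = w.subvec(h * d, h * d + h - 1);
  v = w.subvec(h * d + h, h * d + 2 * h - 1);
  b2 = w(h * d + 2 * h);
}

static mat jacobian(const mat& X, const mat& Z, const vec& v) {
  const int n = X.n_rows, d = X.n_cols, h = Z.n_cols;
  const int p = h * d + 2 * h + 1;
  mat J(n, p);
  mat D = 1.0 - square(Z);  // tanh'
  for (int k = 0; k < h; ++k) {
    vec dk = D.col(k) * v(k);
    for (int j = 0; j < d; ++j) J.col(k + h * j) = dk % X.col(j);
    J.col(h * d + k) = dk;           // d/db1_k
    J.col(h * d + h + k) = Z.col(k); // d/dv_k
  }
  J.col(p - 1).ones();               // d/db2
  return J;
}

// [[Rcpp::export]]
Rcpp::List brnn_fit_cpp(const arma::mat& X, const arma::vec& y,
                        const arma::vec& w_init, int hidden,
                        int maxit = 40, double tol = 1e-6) {
  const int n = X.n_rows, d = X.n_cols, h = hidden;
  const int p = h * d + 2 * h + 1;
  vec w = w_init;
  mat W1; vec b1, v; double b2;
  unpack(w, d, h, W1, b1, v, b2);

  mat Z;
  vec yhat = forward(X, W1, b1, v, b2, Z);
  vec e = y - yhat;
  double ED = dot(e, e), EW = dot(w, w);
  double alpha = 0.01, beta = 1.0, gamma = 0.5 * p;
  double mu = 0.005;
  const double mu_inc = 10.0, mu_dec = 0.1, mu_max = 1e10;
  int iter = 0;
  bool converged = false;

  for (iter = 0; iter < maxit; ++iter) {
    mat J = jacobian(X, Z, v);
    mat JtJ = J.t() * J;
    vec Jte = J.t() * e;
    double F = beta * ED + alpha * EW;
    bool accepted = false;
    vec w_new; double ED_new = ED, EW_new = EW;
    mat Z_new; vec yhat_new, e_new;
    while (mu <= mu_max) {
      mat A = 2.0 * beta * JtJ + (2.0 * alpha + mu) * eye(p, p);
      vec g = 2.0 * beta * Jte - 2.0 * alpha * w;
      vec delta;
      bool ok = solve(delta, A, g, solve_opts::likely_sympd + solve_opts::no_approx);
      if (ok) {
        w_new = w + delta;
        mat W1n; vec b1n, vn; double b2n;
        unpack(w_new, d, h, W1n, b1n, vn, b2n);
        yhat_new = forward(X, W1n, b1n, vn, b2n, Z_new);
        e_new = y - yhat_new;
        ED_new = dot(e_new, e_new);
        EW_new = dot(w_new, w_new);
        double F_new = beta * ED_new + alpha * EW_new;
        if (std::isfinite(F_new) && F_new < F) {
          accepted = true;
          mu = std::max(mu * mu_dec, 1e-12);
          if (max(abs(delta)) < tol) converged = true;
          break;
        }
      }
      mu *= mu_inc;
    }
    if (!accepted) { converged = true; break; }
    w = w_new; e = e_new; yhat = yhat_new; Z = Z_new;
    ED = ED_new; EW = EW_new;

    // evidence update of (alpha, beta); Gauss-Newton Hessian from the last
    // evaluated Jacobian is accurate enough for the hyper-parameter step
    mat H = 2.0 * beta * JtJ + 2.0 * alpha * eye(p, p);
    mat Hinv;
    if (inv_sympd(Hinv, H)) {
      gamma = p - 2.0 * alpha * trace(Hinv);
      gamma = std::min(std::max(gamma, 1e-6), (double)p);
    }
    alpha = std::min(gamma / (2.0 * std::max(EW, 1e-10)), 1e6);
    double denom = 2.0 * std::max(ED, 1e-10);
    beta = std::min(std::max((n - gamma), 1.0) / denom, 1e8);
    if (converged) break;
  }

  unpack(w, d, h, W1, b1, v, b2);
  return Rcpp::List::create(
    Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
    Rcpp::Named("v") = v, Rcpp::Named("b2") = b2,
    Rcpp::Named("alpha") = alpha, Rcpp::Named("beta") = beta,
    Rcpp::Named("gamma") = gamma, Rcpp::Named("sse") = ED,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged);
}

// [[Rcpp::export]]
arma::vec brnn_predict_cpp(const arma::mat& X, const arma::mat& W1,
                           const arma::vec& b1, const arma::vec& v,
                           double b2) {
  mat Z = tanh(X * W1.t() + repmat(b1.t(), X.n_rows, 1));
  return Z * v + b2;
}
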