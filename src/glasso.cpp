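// Block coordinate-descent graphical lasso with an element-wise penalty
// weight matrix. Each column subproblem is a lasso solved by coordinate
// descent with soft-thresholding; zeros in the returned precision matrix are
// exact (produced by thresholding, never by rounding).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// penalized negative log-likelihood; NA if Omega is not numerically PD
static double penalized_obj(const mat& Omega, const mat& S, const mat& Lambda) {
  double ld, sign;
  mat Osym = 0.5 * (Omega + Omega.t());
  bool ok = log_det(ld, sign, Osym);
  if (!ok || sign <= 0) return NA_REAL;
  return -ld + accu(Osym % S) + accu(Lambda % abs(Osym));
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, const arma::mat& Lambda,
                      double eps, int max_outer,
                      double inner_tol, int inner_max,
                      Rcpp::Nullable<Rcpp::NumericMatrix> omega_init = R_NilValue,
                      Rcpp::Nullable<Rcpp::NumericMatrix> sigma_init = R_NilValue) {
  const uword p = S.n_rows;

  mat W, Omega;
  mat B(p, p, fill::zeros);           // warm-started column lasso solutions
  if (omega_init.isNotNull() && sigma_init.isNotNull()) {
    // warm start from a previous solve; the diagonal of the covariance
    // iterate is pinned to its fixed value S_jj + Lambda_jj
    Omega = Rcpp::as<mat>(omega_init.get());
    W = Rcpp::as<mat>(sigma_init.get());
    W.diag() = S.diag() + Lambda.diag();
    for (uword j = 0; j < p; ++j)
      for (uword i = 0; i < p; ++i)
        if (i != j) B(i, j) = -Omega(i, j) / Omega(j, j);
  } else {
    W = S;
    W.diag() += Lambda.diag();        // Sigma_0 = S + diag penalty
    bool ok = inv_sympd(Omega, W);
    if (!ok)
      Rcpp::stop("initial covariance S + diag(penalty) is not positive definite; increase the penalty or apply covariance shrinkage");
  }
  std::vector<double> obj_trace;
  obj_trace.push_back(penalized_obj(Omega, S, Lambda));

  int iter = 0;
  bool converged = false;

  uvec all = regspace<uvec>(0, p - 1);

  for (iter = 1; iter <= max_outer; ++iter) {
    mat Omega_old = Omega;

    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec lam12 = Lambda.col(j);
      lam12 = lam12.elem(idx);

      vec b = B.col(j);
      b = b.elem(idx);
      vec c = W11 * b;                // running W11 %*% b

      for (int pass = 0; pass < inner_max; ++pass) {
        double maxdiff = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double bk_old = b(k);
          double grad = s12(k) - c(k) + W11(k, k) * bk_old;
          double bk = soft(grad, lam12(k)) / W11(k, k);
          if (bk != bk_old) {
            b(k) = bk;
            c += W11.col(k) * (bk - bk_old);
            double d = std::abs(bk - bk_old);
            if (d > maxdiff) maxdiff = d;
          }
        }
        if (maxdiff < inner_tol) break;
      }

      // w12 = W11 * b; reassemble covariance column, then precision column
      vec w12 = c;
      for (uword k = 0; k < p - 1; ++k) {
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = b(k);
      }
      double ojj = 1.0 / (W(j, j) - dot(w12, b));
      Omega(j, j) = ojj;
      for (uword k = 0; k < p - 1; ++k)
        Omega(idx(k), j) = -b(k) * ojj;   // column-only write; exact zeros kept
    }

    obj_trace.push_back(penalized_obj(Omega, S, Lambda));

    double delta = accu(square(Omega - Omega_old));
    if (delta < eps) { converged = true; break; }
  }
  if (iter > max_outer) iter = max_outer;

  // support-preserving symmetrization: both partners nonzero -> average,
  // otherwise both zero (keeps the edge set symmetric and zeros exact)
  mat Osym(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    Osym(j, j) = Omega(j, j);
    for (uword i = j + 1; i < p; ++i) {
      double a = Omega(i, j), bq = Omega(j, i);
      double v = (a != 0.0 && bq != 0.0) ? 0.5 * (a + bq) : 0.0;
      Osym(i, j) = v;
      Osym(j, i) = v;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("Omega") = Osym,
    Rcpp::Named("Sigma") = 0.5 * (W + W.t()),
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("objective_trace") = obj_trace);
}
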