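// Numerical cores for magnitude least-squares shimming.
//
// A is the (in-mask voxels x channels) complex field matrix, m the target
// magnitude vector on the same voxels.  The objective is
//   J(b) = sum_v (| (A b)_v | - m_v)^2 + lambda * ||b||^2
// optimized over the 2*C real degrees of freedom of the complex weight
// vector b.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double mls_objective_cpp(const cx_mat& A, const vec& m,
                                const cx_vec& b, double lambda) {
  cx_vec f = A * b;
  vec r = abs(f) - m;
  return dot(r, r) + lambda * std::real(cdot(b, b));
}

// Gradient of J with respect to (Re b, Im b), returned as a complex vector
// g with dJ/dRe(b_c) = Re(g_c), dJ/dIm(b_c) = Im(g_c).
static cx_vec mls_gradient_cpp(const cx_mat& A, const vec& m,
                               const cx_vec& b, double lambda) {
  cx_vec f = A * b;
  vec mag = abs(f);
  cx_vec phase(f.n_elem);
  for (uword v = 0; v < f.n_elem; ++v) {
    phase[v] = (mag[v] > 1e-300) ? f[v] / mag[v] : cx_double(0.0, 0.0);
  }
  cx_vec weighted = (mag - m) % phase;
  return 2.0 * (A.t() * weighted) + 2.0 * lambda * b;
}

// Multi-restart Adam minimization of J.  `inits` holds one complex start
// per column; each restart runs independently and deterministically.
// [[Rcpp::export]]
Rcpp::List cpp_adam_shim(const arma::cx_mat& A, const arma::vec& m,
                         const arma::cx_mat& inits, double lambda,
                         double lr, double beta1, double beta2, double eps,
                         int max_iters, double tol) {
  const uword C = A.n_cols, K = inits.n_cols;
  cx_mat weights(C, K, fill::zeros);
  vec objective(K);
  ivec iterations(K);

  for (uword k = 0; k < K; ++k) {
    vec x = join_cols(real(inits.col(k)), imag(inits.col(k)));
    vec mt(2 * C, fill::zeros), vt(2 * C, fill::zeros);
    cx_vec b = inits.col(k);
    double obj = mls_objective_cpp(A, m, b, lambda);
    double prev = obj;
    int used = 0;
    for (int t = 1; t <= max_iters; ++t) {
      cx_vec g = mls_gradient_cpp(A, m, b, lambda);
      vec grad = join_cols(real(g), imag(g));
      mt = beta1 * mt + (1.0 - beta1) * grad;
      vt = beta2 * vt + (1.0 - beta2) * square(grad);
      double bc1 = 1.0 - std::pow(beta1, t);
      double bc2 = 1.0 - std::pow(beta2, t);
      x -= lr * (mt / bc1) / (sqrt(vt / bc2) + eps);
      b = cx_vec(x.head(C), x.tail(C));
      obj = mls_objective_cpp(A, m, b, lambda);
      used = t;
      if (!std::isfinite(obj)) break;
      if (std::abs(prev - obj) < tol) break;
      prev = obj;
    }
    weights.col(k) = b;
    objective[k] = obj;
    iterations[k] = used;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = weights,
                            Rcpp::Named("objective") = objective,
                            Rcpp::Named("iterations") = iterations);
}

// [[Rcpp::export]]
double cpp_mls_objective(const arma::cx_mat& A, const arma::vec& m,
                         const arma::cx_vec& b, double lambda) {
  return mls_objective_cpp(A, m, b, lambda);
}

// [[Rcpp::export]]
arma::cx_vec cpp_mls_gradient(const arma::cx_mat& A, const arma::vec& m,
                              const arma::cx_vec& b, double lambda) {
  return mls_gradient_cpp(A, m, b, lambda);
}

// Exhaustive magnitude x phase grid search over 1 or 2 channels with the
// global phase fixed to channel 0.  Independent reference for the
// iterative optimizers; brute force by construction.
// [[Rcpp::export]]
Rcpp::List cpp_grid_search(const arma::cx_mat& A, const arma::vec& m,
                           double lambda, double mag_max, double mag_step,
                           double phase_step_deg) {
  const uword C = A.n_cols, N = A.n_rows;
  if (C < 1 || C > 2)
    Rcpp::stop("grid search supports 1 or 2 channels");
  const int n_mag = (int)std::floor(mag_max / mag_step + 0.5) + 1;
  const int n_ph = (int)std::floor(360.0 / phase_step_deg + 0.5);
  const double deg2rad = datum::pi / 180.0;

  double best = datum::inf;
  cx_vec best_b(C, fill::zeros);

  if (C == 1) {
    for (int i = 0; i < n_mag; ++i) {
      double a0 = i * mag_step;
      double obj = lambda * a0 * a0;
      for (uword v = 0; v < N; ++v) {
        double r = a0 * std::abs(A(v, 0)) - m[v];
        obj += r * r;
      }
      if (obj < best) { best = obj; best_b[0] = cx_double(a0, 0.0); }
    }
  } else {
    // Precompute phase-rotated second-channel columns.
    cx_mat A1ph(N, n_ph);
    for (int p = 0; p < n_ph; ++p) {
      cx_double ph = std::polar(1.0, p * phase_step_deg * deg2rad);
      A1ph.col(p) = A.col(1) * ph;
    }
    for (int i = 0; i < n_mag; ++i) {
      double a0 = i * mag_step;
      cx_vec f0 = a0 * A.col(0);
      for (int j = 0; j < n_mag; ++j) {
        double a1 = j * mag_step;
        double reg = lambda * (a0 * a0 + a1 * a1);
        for (int p = 0; p < n_ph; ++p) {
          double obj = reg;
          const cx_double* col = A1ph.colptr(p);
          for (uword v = 0; v < N; ++v) {
            cx_double f = f0[v] + a1 * col[v];
            double r = std::abs(f) - m[v];
            obj += r * r;
          }
          if (obj < best) {
            best = obj;
            best_b[0] = cx_double(a0, 0.0);
            best_b[1] = a1 * std::polar(1.0, p * phase_step_deg * deg2rad);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("weights") = best_b,
                            Rcpp::Named("objective") = best);
}
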