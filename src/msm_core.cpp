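// Compiled core for the four-state frailty multi-state model.
//
// States are coded 1 = robust, 2 = pre-frail, 3 = frail, 4 = dead.
// Death is absorbing, so every generator has the block form
//   Q = [ Q_TT  q_D ]
//       [  0     0  ]
// and all matrix exponentials are taken on the 3x3 transient block:
// exp(Qt)_TT = exp(Q_TT t), which is what both the interval likelihood
// and the life-expectancy integrator need.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Build the transient block Q_TT and the death-intensity column qd from a
// coefficient matrix B (n_trans x (1 + K): intercept then K covariate
// coefficients, structural zeros where a term is absent) and a covariate
// row x (length K).
static inline void build_q(const mat& B, const rowvec& x, const umat& trans,
                           mat& QTT, vec& qd) {
  QTT.zeros(3, 3);
  qd.zeros(3);
  const uword nt = trans.n_rows;
  for (uword t = 0; t < nt; ++t) {
    double eta = B(t, 0);
    for (uword k = 0; k < x.n_elem; ++k) eta += B(t, k + 1) * x(k);
    // cap the log intensity so that line-search excursions of the
    // optimiser cannot overflow the exponential; 20 corresponds to ~5e8
    // events/year, far beyond any region of interest
    if (eta > 20.0) eta = 20.0;
    const double q = std::exp(eta);
    const uword r = trans(t, 0) - 1;
    const uword s = trans(t, 1);
    if (s == 4) qd(r) += q; else QTT(r, s - 1) += q;
  }
  for (uword r = 0; r < 3; ++r) {
    double tot = qd(r);
    for (uword s = 0; s < 3; ++s) if (s != r) tot += QTT(r, s);
    QTT(r, r) = -tot;
  }
}

// Matrix exponential of the 3x3 transient block of a generator, by
// uniformization with scaling and squaring. For a (sub)generator A with
// lambda = max_r |A(r,r)|, M = I + A/lambda is non-negative with row sums
// <= 1 and exp(A) = e^-lambda * sum_k lambda^k/k! M^k converges without
// cancellation. A is first scaled by 2^s so the effective lambda is <= 5
// (about 40 series terms for ~1e-12 accuracy), then squared s times.
// Unconditionally stable for arbitrarily large intensities, unlike
// Pade/inverse-based routines.
static mat expm_gen3(const mat& A) {
  double lambda = 0.0;
  for (uword r = 0; r < 3; ++r) lambda = std::max(lambda, -A(r, r));
  if (!std::isfinite(lambda)) Rcpp::stop("non-finite intensity matrix");
  if (lambda <= 0.0) return eye(3, 3) + A;  // zero generator
  int s = 0;
  if (lambda > 5.0) s = (int)std::ceil(std::log2(lambda / 5.0));
  const double scale = std::pow(2.0, s);
  const double ls = lambda / scale;
  mat M = A / (scale * ls);
  M.diag() += 1.0;
  mat Mk(3, 3, fill::eye);
  mat S(3, 3, fill::zeros);
  double w = std::exp(-ls);
  // ||M^k|| <= 1 in row-sum norm, so the truncated tail is bounded by the
  // Poisson tail; stop once the weights are negligible
  for (int k = 0;; ++k) {
    S += w * Mk;
    if ((w < 1e-16 && k >= (int)ls) || k > 200) break;
    Mk = Mk * M;
    w *= ls / (k + 1);
  }
  for (int i = 0; i < s; ++i) S = S * S;
  return S;
}

// [[Rcpp::export]]
arma::mat expm_mat(const arma::mat& A) {
  return expmat(A);
}

// Per-interval log-likelihood contributions.
//
// from/to: observed states bracketing each interval; dt: interval length in
// years; is_death = 1 when the interval ends in an exactly observed death,
// in which case the state occupied immediately before death is marginalised:
//   L = sum_k P_{from,k}(dt) * q_{k,dead}(at the death age).
// The survival part P(dt) uses the interval's covariate row X; the terminal
// death hazard uses the age shifted forward by death_shift (the gap between
// the age at which X was evaluated and the death age), since the hazard
// factor is a density at the endpoint, not an interval average. age_col is
// the 0-based age column of X, or -1 when the model has no age term.
// Probabilities are floored at 1e-300 before the log so the optimiser sees a
// finite (hugely penalised) value instead of -Inf.
// [[Rcpp::export]]
arma::vec interval_loglik_cpp(const arma::mat& B, const arma::mat& X,
                              const arma::uvec& from, const arma::uvec& to,
                              const arma::vec& dt, const arma::uvec& is_death,
                              const arma::umat& trans, int age_col,
                              const arma::vec& death_shift) {
  const uword n = from.n_elem;
  vec out(n);
  mat QTT(3, 3), QTT2(3, 3);
  vec qd(3), qd2(3);
  for (uword i = 0; i < n; ++i) {
    build_q(B, X.row(i), trans, QTT, qd);
    const mat P = expm_gen3(QTT * dt(i));
    double lik;
    if (is_death(i) == 1) {
      if (age_col >= 0 && death_shift(i) != 0.0) {
        rowvec x2 = X.row(i);
        x2(age_col) += death_shift(i);
        build_q(B, x2, trans, QTT2, qd2);
        lik = dot(P.row(from(i) - 1), qd2);
      } else {
        lik = dot(P.row(from(i) - 1), qd);
      }
    } else if (to(i) == 4) {
      // death known only to have occurred within the interval
      lik = 1.0 - accu(P.row(from(i) - 1));
    } else {
      lik = P(from(i) - 1, to(i) - 1);
    }
    out(i) = std::log(std::max(lik, 1e-300));
  }
  return out;
}

// Life-expectancy integrator (product integration of the transition
// probability flow). Starting from age0 with covariate row z0, the age
// column (0-based index age_col into z0; -1 when the model has no age term)
// is refreshed at each step's midpoint; other covariates stay fixed. The
// cumulated occupancy P(age0, u) over living states is integrated by the
// trapezoidal rule to give e[r, s] = E(years in s | start in r at age0).
// Returns the 3x3 matrix of state-specific expectancies and the residual
// survival probabilities at age_max (for horizon diagnostics).
// [[Rcpp::export]]
Rcpp::List le_integrate_cpp(const arma::mat& B, const arma::rowvec& z0,
                            int age_col, double age0, double h,
                            double age_max, double age_offset,
                            const arma::umat& trans) {
  mat P(3, 3, fill::eye);
  mat E(3, 3, fill::zeros);
  mat QTT(3, 3);
  vec qd(3);
  rowvec x = z0;
  double u = age0;
  while (u < age_max - 1e-12) {
    const double step = std::min(h, age_max - u);
    if (age_col >= 0) x(age_col) = (u + step / 2.0) - age_offset;
    build_q(B, x, trans, QTT, qd);
    const mat Pnext = P * expm_gen3(QTT * step);
    E += (step / 2.0) * (P + Pnext);
    P = Pnext;
    u += step;
  }
  return Rcpp::List::create(Rcpp::Named("e") = E,
                            Rcpp::Named("surv") = sum(P, 1));
}
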