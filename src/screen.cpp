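// Fast community screening loop: for each species subset, solve the equal-
// fitness equilibrium sigma P = w 1 on the simplex, classify feasibility,
// local stability (reduced Jacobian) and community-level feedback (dominant
// tangent-space eigenvalue of the symmetrized sigma), and accumulate the
// model complementarity, predicted PSF and pathogen dilution.  Mirrors the
// pure-R screen_one_r() used as its oracle in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double community_feedback_arma(const arma::mat& sigma) {
  const arma::uword N = sigma.n_rows;
  arma::mat S = (sigma + sigma.t()) / 2.0;
  arma::mat ones(1, N, arma::fill::ones);
  arma::mat B = arma::null(ones);  // orthonormal basis of the tangent space
  arma::vec ev = arma::eig_sym(B.t() * S * B);
  return ev.max();
}

// [[Rcpp::export]]
NumericMatrix screen_subsets_cpp(const arma::mat& sigma_full,
                                 const arma::mat& psf_full,
                                 List subsets, double w_mono) {
  const int m = subsets.size();
  NumericMatrix out(m, 8);
  const double eps = 1e-9;
  for (int s = 0; s < m; ++s) {
    IntegerVector idx1 = subsets[s];
    const int N = idx1.size();
    arma::uvec idx(N);
    for (int i = 0; i < N; ++i) idx[i] = idx1[i] - 1;
    arma::mat sigma = sigma_full.submat(idx, idx);
    double Ic = community_feedback_arma(sigma);
    out(s, 2) = Ic;
    out(s, 3) = NA_REAL; out(s, 4) = NA_REAL;
    out(s, 5) = NA_REAL; out(s, 6) = NA_REAL;
    arma::vec x;
    bool ok = arma::solve(x, sigma, arma::vec(N, arma::fill::ones),
                          arma::solve_opts::no_approx);
    double tot = ok ? arma::sum(x) : 0.0;
    if (!ok || std::abs(tot) < 1e-12) {
      out(s, 0) = 0; out(s, 1) = 0; out(s, 7) = 1;
      continue;
    }
    arma::vec P = x / tot;
    double w_hat = 1.0 / tot;
    bool feasible = arma::all(P > eps) && arma::all(P < 1 - eps);
    out(s, 0) = feasible ? 1 : 0;
    out(s, 7) = 0;
    if (!feasible) { out(s, 1) = 0; continue; }
    // reduced Jacobian J_ik = P_i (sigma_ik - sigma_iN - (v_k - v_N)),
    // v = P' sigma
    arma::rowvec v = P.t() * sigma;
    arma::mat J(N - 1, N - 1);
    for (int i = 0; i < N - 1; ++i)
      for (int k = 0; k < N - 1; ++k)
        J(i, k) = P[i] * (sigma(i, k) - sigma(i, N - 1) - (v[k] - v[N - 1]));
    arma::cx_vec ev = arma::eig_gen(J);
    double lam = arma::real(ev).max();
    out(s, 1) = (lam < -1e-9) ? 1 : 0;
    out(s, 3) = w_hat;
    out(s, 4) = N * (w_hat - w_mono);
    double pred = 0.0;
    arma::mat psf = psf_full.submat(idx, idx);
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j)
        pred += P[i] * P[j] * psf(i, j);
    out(s, 5) = pred;
    out(s, 6) = -pred * (1.0 - 1.0 / N);
  }
  return out;
}
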