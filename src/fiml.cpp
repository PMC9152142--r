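// RAM-parameterized FIML objective and analytic gradient.
//
// A multigroup model is passed down as a list of group structures holding
// fixed RAM matrices (A: directed paths, S: symmetric covariances, M: means),
// sparse parameter position maps, and per-missingness-pattern sufficient
// statistics (n, sum, raw cross-product sum).  The objective is
//   -2 lnL = sum_p [ n_p k_p log(2*pi) + n_p log|Sigma_p| + tr(Sigma_p^-1 W_p) ]
// with Sigma_p, mu_p the implied moments restricted to the pattern's observed
// variables and W_p the centered scatter about mu_p.  The gradient exploits
// the RAM chain rule: with B = (I-A)^-1, C = B S B', m = B M,
//   d(-2lnL)/dA[i,j] = 2 (C G B)[j,i] - 2 v[i] m[j]
//   d(-2lnL)/dS[i,j] = (B' G B)[i,j] * (1 + (i != j))
//   d(-2lnL)/dM[i]   = -2 v[i]
// where G accumulates n_p Sigma_p^-1 - Sigma_p^-1 W_p Sigma_p^-1 scattered to
// full variable space, u accumulates Sigma_p^-1 (s_p - n_p mu_p), v = B' u.
//
// Non-positive-definite implied covariances return a large finite penalty so
// bounded quasi-Newton line searches can back off.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

static const double LOG2PI = 1.8378770664093454836;
static const double PENALTY = 1e12;

// [[Rcpp::export(name = ".ram_fiml")]]
Rcpp::List ram_fiml(const arma::vec& theta, const Rcpp::List& groups,
                    bool want_grad) {
  const int npar = theta.n_elem;
  double value = 0.0;
  arma::vec grad(npar, arma::fill::zeros);
  bool ok = true;

  for (int g = 0; g < groups.size(); ++g) {
    Rcpp::List grp = groups[g];
    arma::mat A = Rcpp::as<arma::mat>(grp["A0"]);
    arma::mat S = Rcpp::as<arma::mat>(grp["S0"]);
    arma::vec M = Rcpp::as<arma::vec>(grp["M0"]);
    arma::imat pA = Rcpp::as<arma::imat>(grp["pA"]);
    arma::imat pS = Rcpp::as<arma::imat>(grp["pS"]);
    arma::imat pM = Rcpp::as<arma::imat>(grp["pM"]);
    arma::uvec man = Rcpp::as<arma::uvec>(grp["man"]);
    Rcpp::List patterns = grp["patterns"];
    const int nv = A.n_rows;

    for (arma::uword r = 0; r < pA.n_rows; ++r)
      A(pA(r, 1), pA(r, 2)) = theta(pA(r, 0));
    for (arma::uword r = 0; r < pS.n_rows; ++r) {
      S(pS(r, 1), pS(r, 2)) = theta(pS(r, 0));
      S(pS(r, 2), pS(r, 1)) = theta(pS(r, 0));
    }
    for (arma::uword r = 0; r < pM.n_rows; ++r)
      M(pM(r, 1)) = theta(pM(r, 0));

    arma::mat B;
    bool inv_ok = arma::inv(B, arma::eye(nv, nv) - A);
    if (!inv_ok) { ok = false; break; }
    arma::mat C = B * S * B.t();
    arma::vec mu_full = B * M;
    arma::mat Cm = C.submat(man, man);
    arma::vec mu_m = mu_full.elem(man);
    const int nman = man.n_elem;

    arma::mat Gman(nman, nman, arma::fill::zeros);
    arma::vec uman(nman, arma::fill::zeros);

    for (int p = 0; p < patterns.size(); ++p) {
      Rcpp::List pat = patterns[p];
      arma::uvec obs = Rcpp::as<arma::uvec>(pat["obs"]);
      double n = Rcpp::as<double>(pat["n"]);
      arma::vec s = Rcpp::as<arma::vec>(pat["s"]);
      arma::mat SS = Rcpp::as<arma::mat>(pat["SS"]);
      const int k = obs.n_elem;

      arma::mat Sig = Cm.submat(obs, obs);
      arma::vec mu = mu_m.elem(obs);
      arma::mat L;
      if (!arma::chol(L, Sig, "lower")) { ok = false; break; }
      double logdet = 2.0 * arma::accu(arma::log(L.diag()));
      arma::mat Si = arma::inv_sympd(Sig);
      arma::mat W = SS - s * mu.t() - mu * s.t() + n * (mu * mu.t());
      value += n * k * LOG2PI + n * logdet + arma::trace(Si * W);

      if (want_grad) {
        arma::mat Gp = n * Si - Si * W * Si;
        arma::vec up = Si * (s - n * mu);
        Gman.submat(obs, obs) += Gp;
        uman.elem(obs) += up;
      }
    }
    if (!ok) break;

    if (want_grad) {
      arma::mat Gfull(nv, nv, arma::fill::zeros);
      arma::vec ufull(nv, arma::fill::zeros);
      Gfull.submat(man, man) = Gman;
      ufull.elem(man) = uman;
      arma::mat TS = B.t() * Gfull * B;        // for S entries
      arma::mat TA = C * Gfull * B;            // for A entries (Sigma part)
      arma::vec v = B.t() * ufull;             // for mean parts

      for (arma::uword r = 0; r < pA.n_rows; ++r) {
        int i = pA(r, 1), j = pA(r, 2);
        grad(pA(r, 0)) += 2.0 * TA(j, i) - 2.0 * v(i) * mu_full(j);
      }
      for (arma::uword r = 0; r < pS.n_rows; ++r) {
        int i = pS(r, 1), j = pS(r, 2);
        grad(pS(r, 0)) += TS(i, j) * (i == j ? 1.0 : 2.0);
      }
      for (arma::uword r = 0; r < pM.n_rows; ++r)
        grad(pM(r, 0)) += -2.0 * v(pM(r, 1));
    }
  }

  if (!ok) {
    value = PENALTY;
    grad.zeros();
  }
  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("gradient") = grad,
                            Rcpp::Named("ok") = ok);
}
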