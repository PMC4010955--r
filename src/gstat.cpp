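// Vectorised computation of the heteroscedasticity-robust G statistic
// across the V simultaneous tests of one shuffle. Per column: group
// weights from the residual sums of squares, M'WM as a weighted sum of
// fixed per-group cross-products, the contrast quadratic form, and the
// Welch-type correction Lambda.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// q     : s x V  contrast effects C' psi
// rssg  : k x V  per-group residual sums of squares
// dfg   : k      per-group sums of the residual-forming matrix diagonal
// ng    : k      group sizes
// Astack: r x r x k  per-group design cross-products sum_{n in g} m_n m_n'
// Cp    : r x s  contrast in the fitted coefficient space
// [[Rcpp::export]]
arma::vec gstat_columns(const arma::mat& q, const arma::mat& rssg,
                        const arma::vec& dfg, const arma::vec& ng,
                        const arma::cube& Astack, const arma::mat& Cp) {
  const arma::uword s = q.n_rows, V = q.n_cols, k = rssg.n_rows,
                    r = Astack.n_rows;
  arma::vec out(V);
  const double lam_fac = 2.0 * (double(s) - 1.0) / (double(s) * (double(s) + 2.0));
  arma::mat MtWM(r, r), K(r, r), S(s, s);
  arma::vec wg(k);
  for (arma::uword v = 0; v < V; ++v) {
    bool degenerate = false;
    for (arma::uword g = 0; g < k; ++g) {
      double rss = rssg(g, v);
      if (rss <= 0.0) { degenerate = true; break; }
      wg(g) = dfg(g) / rss;
    }
    if (degenerate) { out(v) = arma::datum::inf; continue; }
    MtWM.zeros();
    for (arma::uword g = 0; g < k; ++g) MtWM += wg(g) * Astack.slice(g);
    if (!arma::inv_sympd(K, MtWM) && !arma::inv(K, MtWM)) {
      out(v) = arma::datum::nan; continue;
    }
    S = Cp.t() * K * Cp;
    arma::vec qv = q.col(v);
    arma::vec sol;
    if (!arma::solve(sol, S, qv)) { out(v) = arma::datum::nan; continue; }
    double num = arma::dot(qv, sol);
    // Lambda: sum_g (1/dfg) (1 - n_g w_g / trace(W))^2
    double trW = arma::dot(ng, wg);
    double lam = 1.0;
    if (s > 1) {
      double acc = 0.0;
      for (arma::uword g = 0; g < k; ++g) {
        double d = 1.0 - ng(g) * wg(g) / trW;
        acc += d * d / dfg(g);
      }
      lam += lam_fac * acc;
    }
    out(v) = num / (lam * double(s));
  }
  return out;
}
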