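// Median / quantile polynomial regression by pinball-loss minimization.
//
// Two-stage solver: a smoothed iteratively reweighted least-squares pass,
// then an exact "vertex" polish. A quantile-regression optimum interpolates
// p observations (a basis solution of the equivalent linear program), so the
// polish enumerates p-subsets of the lowest-|residual| observations after
// IRLS and keeps the pinball-loss argmin, giving LP-exact coefficients.

#define ARMA_WARN_LEVEL 0  // singular interpolation subsets are expected and skipped
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double pinball(const arma::vec& r, double tau) {
  double s = 0.0;
  for (arma::uword i = 0; i < r.n_elem; ++i)
    s += r[i] * (tau - (r[i] < 0 ? 1.0 : 0.0));
  return s;
}

static bool irls(const arma::mat& X, const arma::vec& y, double tau,
                 double tol, int maxit, arma::vec& beta) {
  const arma::uword n = X.n_rows;
  if (!arma::solve(beta, X, y)) return false;  // OLS start
  double eps = 1e-4;
  arma::vec best = beta;
  double best_loss = pinball(y - X * beta, tau);
  for (int it = 0; it < maxit; ++it) {
    arma::vec r = y - X * beta;
    arma::vec w(n);
    for (arma::uword i = 0; i < n; ++i) {
      double a = std::abs(r[i]);
      if (a < eps) a = eps;
      w[i] = (r[i] > 0 ? tau : 1.0 - tau) / a;
    }
    arma::mat Xw = X.each_col() % w;
    arma::vec bnew;
    if (!arma::solve(bnew, X.t() * Xw, X.t() * (w % y))) break;
    double loss = pinball(y - X * bnew, tau);
    if (loss < best_loss) { best_loss = loss; best = bnew; }
    double step = arma::norm(bnew - beta);
    beta = bnew;
    if (step < tol * (1.0 + arma::norm(beta)) && eps <= 1e-10) break;
    eps = std::max(eps * 0.3, 1e-12);
  }
  beta = best;
  return true;
}

// enumerate p-subsets of candidate rows, solve the interpolation system,
// keep the pinball-loss minimiser (ties: minimum coefficient norm)
static void vertex_polish(const arma::mat& X, const arma::vec& y, double tau,
                          arma::vec& beta, bool& nonunique, int m_cand) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec r = y - X * beta;
  arma::uvec ord = arma::sort_index(arma::abs(r));
  int m = std::min(n, m_cand);
  double best_loss = pinball(r, tau);
  arma::vec best = beta;
  nonunique = false;
  std::vector<int> comb(p);
  for (int i = 0; i < p; ++i) comb[i] = i;
  arma::mat Xs(p, p);
  arma::vec ys(p), cand;
  while (true) {
    for (int i = 0; i < p; ++i) {
      Xs.row(i) = X.row(ord[comb[i]]);
      ys[i] = y[ord[comb[i]]];
    }
    if (arma::solve(cand, Xs, ys, arma::solve_opts::no_approx)) {
      double loss = pinball(y - X * cand, tau);
      if (loss < best_loss - 1e-12) {
        best_loss = loss; best = cand; nonunique = false;
      } else if (std::abs(loss - best_loss) <= 1e-12 &&
                 arma::norm(cand - best) > 1e-8) {
        nonunique = true;
        if (arma::norm(cand) < arma::norm(best)) best = cand;
      }
    }
    // next combination
    int i = p - 1;
    while (i >= 0 && comb[i] == m - p + i) --i;
    if (i < 0) break;
    ++comb[i];
    for (int j = i + 1; j < p; ++j) comb[j] = comb[j - 1] + 1;
  }
  beta = best;
}

// [[Rcpp::export(name = ".qr_fit_cpp")]]
List qr_fit_cpp(const arma::mat& X, const arma::vec& y, double tau,
                bool polish = true, double tol = 1e-8, int maxit = 200,
                int m_cand = 18) {
  arma::vec beta;
  if (!irls(X, y, tau, tol, maxit, beta))
    stop("singular design: insufficient distinct dose levels");
  bool nonunique = false;
  if (polish) vertex_polish(X, y, tau, beta, nonunique, m_cand);
  return List::create(_["coef"] = beta,
                      _["loss"] = pinball(y - X * beta, tau),
                      _["nonunique"] = nonunique);
}

// case-resampling bootstrap of the IRLS fit; uses the R RNG
// [[Rcpp::export(name = ".qr_boot_cpp")]]
arma::mat qr_boot_cpp(const arma::mat& X, const arma::vec& y, double tau,
                      int n_boot, double tol = 1e-8, int maxit = 200) {
  const int n = X.n_rows, p = X.n_cols;
  arma::mat out(n_boot, p);
  arma::mat Xb(n, p);
  arma::vec yb(n), beta;
  for (int b = 0; b < n_boot; ++b) {
    bool ok = false;
    for (int tries = 0; tries < 20 && !ok; ++tries) {
      for (int i = 0; i < n; ++i) {
        int j = (int)(unif_rand() * n);
        if (j == n) j = n - 1;
        Xb.row(i) = X.row(j);
        yb[i] = y[j];
      }
      ok = irls(Xb, yb, tau, tol, maxit, beta);
    }
    if (!ok) stop("bootstrap resample produced a singular design repeatedly");
    out.row(b) = beta.t();
  }
  return out;
}
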