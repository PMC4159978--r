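#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Solve one small weighted least-squares system per voxel (column).
// X: (points x p) shared design; Y: (points x V) log signals;
// W: (points x V) non-negative weights. Returns p x V coefficients, the
// minimized weighted residual sum of squares, and a per-voxel success flag
// (false when fewer than p points carry positive weight or the normal
// equations are singular).
// [[Rcpp::export]]
List batch_wls(const arma::mat& X, const arma::mat& Y, const arma::mat& W) {
    const arma::uword r = X.n_rows, p = X.n_cols, V = Y.n_cols;
    if (Y.n_rows != r || W.n_rows != r || W.n_cols != V)
        stop("dimension mismatch between design, data and weights");
    arma::mat coef(p, V, arma::fill::value(arma::datum::nan));
    arma::rowvec rss(V);
    rss.fill(arma::datum::nan);
    LogicalVector ok(V);
    arma::mat A(p, p);
    arma::vec b(p), beta(p), res(r);
    for (arma::uword v = 0; v < V; ++v) {
        const arma::vec w = W.col(v);
        if (arma::accu(w > 0.0) < p) { ok[v] = false; continue; }
        const arma::vec y = Y.col(v);
        const arma::mat Xw = X.each_col() % w;      // diag(w) * X
        A = X.t() * Xw;
        b = Xw.t() * y;
        const bool solved = arma::solve(beta, A, b,
            arma::solve_opts::no_approx + arma::solve_opts::likely_sympd);
        if (!solved || !beta.is_finite()) { ok[v] = false; continue; }
        coef.col(v) = beta;
        res = y - X * beta;
        rss(v) = arma::dot(w, res % res);
        ok[v] = true;
    }
    return List::create(_["coef"] = coef, _["rss"] = rss, _["ok"] = ok);
}
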