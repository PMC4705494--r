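// Iteratively reweighted least squares with Tukey bisquare weights, and a
// batched leave-one-subject-out scorer used by the exhaustive subset search.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Robust residual scale: median of the largest n - p + 1 absolute
// (leverage-adjusted) residuals, divided by 0.6745 so the estimate is
// consistent for the Gaussian SD.
static double mad_sigma(const vec& r, const unsigned int p) {
  vec a = sort(abs(r));
  unsigned int n = a.n_elem;
  unsigned int start = std::min(p >= 1 ? p - 1 : 0, n - 1);
  return median(a.subvec(start, n - 1)) / 0.6745;
}

// Weighted normal-equation solve via Cholesky; returns false when the
// (weighted) design is numerically singular.
static bool wls_solve(const mat& X, const vec& y, const vec* w, vec& b,
                      mat* XtXinv = nullptr) {
  const uword p = X.n_cols;
  mat XtX(p, p);
  vec Xty(p);
  if (w) {
    mat Xw = X.each_col() % (*w);
    XtX = X.t() * Xw;
    Xty = Xw.t() * y;
  } else {
    XtX = X.t() * X;
    Xty = X.t() * y;
  }
  mat L;
  if (!chol(L, XtX, "lower")) return false;
  if (abs(L.diag()).min() < 1e-8 * std::max(1.0, abs(L.diag()).max()))
    return false;
  b = solve(trimatl(L), Xty);
  b = solve(trimatu(L.t()), b);
  if (XtXinv) {
    mat Linv = inv(trimatl(L));
    *XtXinv = Linv.t() * Linv;
  }
  return true;
}

// Returns 0 on rank failure, 1 on convergence, 2 on iteration cap.
static int irls_core(const mat& X, const vec& y, double tune, double tol,
                     int maxit, vec& b, int& iters) {
  mat XtXinv;
  if (!wls_solve(X, y, nullptr, b, &XtXinv)) return 0;
  // leverage h_i = x_i' (X'X)^{-1} x_i, for the residual adjustment
  const uword n = X.n_rows;
  vec adj(n);
  for (uword i = 0; i < n; ++i) {
    double h = as_scalar(X.row(i) * XtXinv * X.row(i).t());
    h = std::min(std::max(h, 0.0), 0.9999);
    adj(i) = 1.0 / std::sqrt(1.0 - h);
  }
  const unsigned int p = X.n_cols;
  iters = 0;
  vec r(n), radj(n), w(n), bnew;
  for (int it = 1; it <= maxit; ++it) {
    iters = it;
    r = y - X * b;
    radj = r % adj;
    double s = mad_sigma(radj, p);
    if (s < 1e-12) return 1;  // (near-)perfect fit: keep current coefficients
    double ts = tune * s;
    double wsum = 0.0;
    for (uword i = 0; i < n; ++i) {
      double u = radj(i) / ts;
      double a = std::abs(u);
      w(i) = a < 1.0 ? (1.0 - u * u) * (1.0 - u * u) : 0.0;
      wsum += w(i);
    }
    if (wsum < 1e-10) return 1;  // everything down-weighted; stop
    if (!wls_solve(X, y, &w, bnew)) return 0;
    double delta = abs(bnew - b).max();
    b = bnew;
    if (delta < tol) return 1;
  }
  return 2;
}

// [[Rcpp::export]]
Rcpp::List irls_fit_cpp(const arma::mat& X, const arma::vec& y, double tune,
                        double tol, int maxit) {
  vec b;
  int iters = 0;
  int status = irls_core(X, y, tune, tol, maxit, b, iters);
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = b,
      Rcpp::Named("status") = status,
      Rcpp::Named("iterations") = iters,
      Rcpp::Named("converged") = (status == 1));
}

// Scores every candidate feature subset by leave-one-subject-out CV.
// F: instances x features; fold: 0-based subject fold id per instance;
// subsets: n_subsets x max_k matrix of 1-based column indices, 0-padded.
// Per-fold mode: mean over folds of sqrt(SS_res / max(N_test - 2, 1));
// pooled mode: sqrt(total SS_res / (N - 2)). A failed fit scores Inf.
// [[Rcpp::export]]
arma::vec loso_scores_cpp(const arma::mat& F, const arma::vec& y,
                          const arma::ivec& fold, const arma::imat& subsets,
                          double tune, double tol, int maxit, bool pooled) {
  const int nfold = fold.max() + 1;
  const uword n = F.n_rows;
  // per-fold train/test feature blocks, computed once
  std::vector<mat> Ftr(nfold), Fte(nfold);
  std::vector<vec> ytr(nfold), yte(nfold);
  for (int f = 0; f < nfold; ++f) {
    std::vector<uword> te, tr;
    for (uword i = 0; i < n; ++i) {
      if (fold(i) == f) te.push_back(i); else tr.push_back(i);
    }
    Ftr[f] = F.rows(uvec(tr));
    Fte[f] = F.rows(uvec(te));
    ytr[f] = y(uvec(tr));
    yte[f] = y(uvec(te));
  }
  const uword ns = subsets.n_rows;
  vec scores(ns);
  for (uword sidx = 0; sidx < ns; ++sidx) {
    if (sidx % 256 == 0) Rcpp::checkUserInterrupt();
    std::vector<uword> cols;
    for (uword j = 0; j < subsets.n_cols; ++j) {
      int c = subsets(sidx, j);
      if (c > 0) cols.push_back(static_cast<uword>(c - 1));
    }
    const uword p = cols.size() + 1;
    double acc = 0.0;
    double pooled_ss = 0.0;
    bool ok = true;
    for (int f = 0; f < nfold; ++f) {
      mat Xtr(Ftr[f].n_rows, p);
      Xtr.col(0).ones();
      for (uword j = 0; j < cols.size(); ++j) Xtr.col(j + 1) = Ftr[f].col(cols[j]);
      vec b;
      int iters = 0;
      int status = irls_core(Xtr, ytr[f], tune, tol, maxit, b, iters);
      if (status == 0) { ok = false; break; }
      mat Xte(Fte[f].n_rows, p);
      Xte.col(0).ones();
      for (uword j = 0; j < cols.size(); ++j) Xte.col(j + 1) = Fte[f].col(cols[j]);
      vec resid = yte[f] - Xte * b;
      double ss = dot(resid, resid);
      if (pooled) {
        pooled_ss += ss;
      } else {
        double denom = std::max(static_cast<double>(resid.n_elem) - 2.0, 1.0);
        acc += std::sqrt(ss / denom);
      }
    }
    if (!ok) {
      scores(sidx) = datum::inf;
    } else if (pooled) {
      scores(sidx) = std::sqrt(pooled_ss / std::max(static_cast<double>(n) - 2.0, 1.0));
    } else {
      scores(sidx) = acc / nfold;
    }
  }
  return scores;
}
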