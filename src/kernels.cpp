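#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// CCIPCA single-frame update (candid covariance-free incremental PCA).
//
// V holds the component estimates in its COLUMNS (n pixels x k components);
// columns beyond `nseeded` are not yet initialised. The update for component r
// at time point i is
//     v_r <- ((i-1)/i) v_r + (1/i) * x * (x' v_r / ||v_r||)
// after which the working copy of the frame is downdated by its projection
// onto the updated (unit-normalised) v_r, so that component r+1 sees the
// residual. Unseeded columns are initialised from the residual of the incoming
// frame after Gram-Schmidt against all seeded columns (deterministic,
// data-driven initialisation); a frame whose residual norm falls below `tol`
// does not seed a component. A seeded column whose norm has collapsed below
// `tol` is re-seeded from the current residual, so no division by zero occurs.
//
// V is modified in place (the caller owns an unshared matrix); the frame is
// copied and never modified. Returns the new seeded-column count.
// [[Rcpp::export]]
int ccipca_update_inplace(Rcpp::NumericMatrix V_, int nseeded,
                          Rcpp::NumericVector x_, int i, double tol,
                          double amnesic = 0.0) {
  const int n = V_.nrow(), k = V_.ncol();
  if (x_.size() != n) Rcpp::stop("frame length does not match component matrix");
  if (i < 1) Rcpp::stop("time point index must be >= 1");
  arma::mat V(V_.begin(), n, k, false, true);   // no copy: in-place update
  arma::vec u(x_.begin(), n);                   // working copy of the frame
  // amnesic > 0 downweights history (higher weight on recent time points);
  // 0 gives the plain 1/i running average
  const double l = (i > amnesic + 1.0) ? amnesic : 0.0;
  const double w_old = ((double)i - 1.0 - l) / (double)i;
  const double w_new = (1.0 + l) / (double)i;
  // ||u||^2 is tracked analytically through the downdates (refreshed
  // periodically against drift) so each component costs two passes: one to
  // read the inner products, one fused update + downdate
  double uu = arma::dot(u, u);
  for (int r = 0; r < nseeded; ++r) {
    if ((r & 7) == 7) uu = arma::dot(u, u);
    double *v = V.colptr(r);
    const double *up = u.memptr();
    double nv2_old = 0.0, proj_raw = 0.0;
    for (int j = 0; j < n; ++j) {
      nv2_old += v[j] * v[j];
      proj_raw += up[j] * v[j];
    }
    if (nv2_old < tol * tol) {      // degenerate component: re-seed from residual
      if (uu > tol * tol) { V.col(r) = u; u.zeros(); uu = 0.0; }
      continue;
    }
    const double beta = w_new * proj_raw / std::sqrt(nv2_old);
    const double nv2_new = w_old * w_old * nv2_old +
      2.0 * w_old * beta * proj_raw + beta * beta * uu;
    const double uv_new = w_old * proj_raw + beta * uu;
    const double d = (nv2_new > tol * tol) ? uv_new / nv2_new : 0.0;
    double *um = u.memptr();
    for (int j = 0; j < n; ++j) {
      double vn = w_old * v[j] + beta * um[j];
      v[j] = vn;
      um[j] -= d * vn;
    }
    if (nv2_new > tol * tol) {
      uu -= uv_new * uv_new / nv2_new;
      if (uu < 0.0) uu = 0.0;
    }
  }
  if (nseeded < k) {
    double nu = arma::norm(u);
    if (nu > tol) { V.col(nseeded) = u; ++nseeded; }
  }
  return nseeded;
}

// Greedy convex-cone extreme-column selection.
//
// M is d x n with the n candidate columns (pixel vectors). Each round picks
// the residual column of largest Euclidean norm (ties broken by lowest index),
// appends its unit-normalised version to the basis, records the projection
// coefficients of ALL columns onto it as a row of S, and subtracts that
// projection from the working matrix. Because each basis vector is drawn from
// a matrix already orthogonal to the previous picks, the basis is orthonormal
// and row j of S equals b_j' M for the ORIGINAL M.
//
// Columns whose residual norm drops below tol_rel times the initial maximum
// norm are ineligible; if no eligible column remains before c picks the
// result is truncated and `complete` is FALSE.
// [[Rcpp::export]]
Rcpp::List convex_cone_cpp(Rcpp::NumericMatrix M_, int c, double tol_rel) {
  const int d = M_.nrow(), n = M_.ncol();
  if (c < 1) Rcpp::stop("c must be >= 1");
  arma::mat W(M_.begin(), d, n, true);          // working copy, downdated
  arma::rowvec norms2 = arma::sum(arma::square(W), 0);
  const double max0 = norms2.max();
  const double cut2 = tol_rel * tol_rel * max0;

  arma::uvec sel(c, arma::fill::zeros);
  arma::mat B(d, c, arma::fill::zeros);
  arma::mat S(c, n, arma::fill::zeros);
  arma::vec maxnorm(c, arma::fill::zeros);
  int nsel = 0;
  for (int j = 0; j < c; ++j) {
    if ((j & 15) == 15)                          // refresh against drift
      norms2 = arma::sum(arma::square(W), 0);
    int p = 0; double best = norms2[0];
    for (int q = 1; q < n; ++q)
      if (norms2[q] > best) { best = norms2[q]; p = q; }
    if (!(best > cut2) || best <= 0.0) break;
    maxnorm[j] = std::sqrt(best);
    arma::vec b = W.col(p) / std::sqrt(arma::dot(W.col(p), W.col(p)));
    arma::rowvec proj = b.t() * W;
    W -= b * proj;
    norms2 -= arma::square(proj);
    norms2.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    norms2[p] = 0.0;
    sel[j] = (arma::uword)p;
    B.col(j) = b;
    S.row(j) = proj;
    ++nsel;
  }
  arma::uvec sel_out = sel.head(nsel) + 1;       // 1-based for R
  return Rcpp::List::create(
      Rcpp::Named("selected") = Rcpp::IntegerVector(sel_out.begin(), sel_out.end()),
      Rcpp::Named("basis") = Rcpp::wrap(arma::mat(B.cols(0, std::max(nsel, 1) - 1))),
      Rcpp::Named("S") = Rcpp::wrap(arma::mat(S.rows(0, std::max(nsel, 1) - 1))),
      Rcpp::Named("max_residual_norm") = Rcpp::wrap(arma::vec(maxnorm.head(std::max(nsel, 1)))),
      Rcpp::Named("complete") = (nsel == c));
}

// Process a chunk of frames through the full per-frame pipeline:
// spatial smoothing (frame image X, stored W x H column-major so that the
// flattened row-major pixel vector is contiguous, is filtered as
// Sc * X * Sr'), one-pass z-score normalisation with the running statistics,
// and the CCIPCA component update. State (V, mean, m2) is updated in place;
// the arithmetic per frame matches the scalar R path. `istart` is the
// 1-based stream index of the chunk's first frame; frames with index <=
// warmup only update the normaliser. Returns the new seeded-component count.
// [[Rcpp::export]]
int stream_chunk_inplace(Rcpp::NumericMatrix At_, Rcpp::NumericMatrix V_,
                         int nseeded, Rcpp::NumericVector mean_,
                         Rcpp::NumericVector m2_, int istart, int warmup,
                         Rcpp::NumericMatrix Sr_, Rcpp::NumericMatrix Sc_,
                         bool do_filter, double sigma_floor, double amnesic) {
  const int n = At_.nrow(), nframes = At_.ncol();
  const int H = Sr_.nrow(), W = Sc_.nrow();
  if (do_filter && H * W != n) Rcpp::stop("smoother dimensions do not match");
  arma::mat At(At_.begin(), n, nframes, false, true);
  arma::mat Sr(Sr_.begin(), H, Sr_.ncol(), false, true);
  arma::mat Sc(Sc_.begin(), W, Sc_.ncol(), false, true);
  double *mu = mean_.begin(), *m2 = m2_.begin();
  arma::vec z(n);
  for (int f = 0; f < nframes; ++f) {
    const int i = istart + f;
    arma::vec x = At.col(f);                      // copy: raw frame untouched
    if (do_filter) {
      arma::mat X(x.memptr(), W, H, false, true);
      arma::mat Xf = (Sc * X) * Sr.t();   // same grouping as the scalar path
      X = Xf;
    }
    for (int j = 0; j < n; ++j) {                 // Welford + z-score
      double delta = x[j] - mu[j];
      mu[j] += delta / i;
      m2[j] += delta * (x[j] - mu[j]);
      double sdv = std::sqrt(m2[j] / i);
      if (sdv < sigma_floor) sdv = sigma_floor;
      z[j] = (x[j] - mu[j]) / sdv;
    }
    if (i <= warmup) continue;
    Rcpp::NumericVector zr(z.begin(), z.end());
    nseeded = ccipca_update_inplace(V_, nseeded, zr, i, 1e-12, amnesic);
  }
  return nseeded;
}

// One-pass (Welford) normalisation update, in place, for the streaming driver.
// mean/m2 are the running per-pixel mean and sum of squared deviations; the
// z-scored frame (population sd, floored at sigma_floor) is written into out.
// [[Rcpp::export]]
int welford_update_inplace(Rcpp::NumericVector mean_, Rcpp::NumericVector m2_,
                           int count, Rcpp::NumericVector x_,
                           Rcpp::NumericVector out_, double sigma_floor) {
  const int n = mean_.size();
  if (x_.size() != n || m2_.size() != n || out_.size() != n)
    Rcpp::stop("length mismatch in normalisation update");
  double *mu = mean_.begin(), *m2 = m2_.begin();
  const double *x = x_.begin();
  double *out = out_.begin();
  const int cnt = count + 1;
  for (int j = 0; j < n; ++j) {
    double delta = x[j] - mu[j];
    mu[j] += delta / cnt;
    m2[j] += delta * (x[j] - mu[j]);
    double sd = std::sqrt(m2[j] / cnt);
    if (sd < sigma_floor) sd = sigma_floor;
    out[j] = (x[j] - mu[j]) / sd;
  }
  return cnt;
}
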