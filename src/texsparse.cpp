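// Numerical core: nonnegative sparse coding, pooling geometry, and the
// permutation machinery that would be too slow in interpreted code.
#include <RcppArmadillo.h>

using namespace Rcpp;

// Solve min_s ||x - A s||^2 + lambda ||s||_1, s >= 0, by cyclic coordinate
// descent on the Gram matrix. Stationarity for s_i > 0 requires
// 2 (G s)_i - 2 c_i + lambda = 0 with G = A'A, c = A'x, so the update is
// s_i <- max(0, (c_i - sum_{k != i} G_ik s_k - lambda/2) / G_ii).
// [[Rcpp::export]]
arma::mat encode_batch_cpp(const arma::mat& A, const arma::mat& X,
                           double lambda, int max_iter, double tol) {
  const arma::uword M = A.n_cols, K = X.n_cols;
  arma::mat G = A.t() * A;
  arma::mat C = A.t() * X;
  arma::mat S(M, K, arma::fill::zeros);
  arma::vec gdiag = G.diag();

  for (arma::uword j = 0; j < K; ++j) {
    arma::vec s(M, arma::fill::zeros);
    arma::vec gs(M, arma::fill::zeros);  // G s, maintained incrementally
    for (int it = 0; it < max_iter; ++it) {
      double delta = 0.0;
      for (arma::uword i = 0; i < M; ++i) {
        if (gdiag(i) <= 1e-12) { continue; }
        double num = C(i, j) - (gs(i) - gdiag(i) * s(i)) - lambda / 2.0;
        double snew = num > 0.0 ? num / gdiag(i) : 0.0;
        double d = snew - s(i);
        if (d != 0.0) {
          gs += G.col(i) * d;
          s(i) = snew;
          double ad = std::abs(d);
          if (ad > delta) delta = ad;
        }
      }
      if (delta < tol) break;
    }
    S.col(j) = s;
  }
  return S;
}

// One pass of block coordinate descent on the dictionary columns given the
// sufficient statistics XSt = X S' and SSt = S S' (Mairal et al. style
// update), followed by projection onto the unit ball ||a_i|| <= 1. The
// update minimises the quadratic objective in a_j under the constraint, so
// the training objective cannot increase. Columns whose code is never
// active (SSt_jj ~ 0) are left untouched.
// [[Rcpp::export]]
arma::mat dict_update_cpp(const arma::mat& A0, const arma::mat& XSt,
                          const arma::mat& SSt) {
  arma::mat A = A0;
  const arma::uword M = A.n_cols;
  for (arma::uword j = 0; j < M; ++j) {
    double d = SSt(j, j);
    if (d <= 1e-12) continue;
    arma::vec u = A.col(j) + (XSt.col(j) - A * SSt.col(j)) / d;
    double nrm = arma::norm(u, 2);
    if (nrm > 1.0) u /= nrm;
    A.col(j) = u;
  }
  return A;
}

// Extract all k x k x C patches at the given stride as columns, with
// optional asymmetric zero padding (left/right = columns, top/bottom = rows).
// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::cube& x, int k, int stride,
                     int pad_top, int pad_bottom, int pad_left, int pad_right) {
  const int h = x.n_rows + pad_top + pad_bottom;
  const int w = x.n_cols + pad_left + pad_right;
  const int nc = x.n_slices;
  const int oh = (h - k) / stride + 1;
  const int ow = (w - k) / stride + 1;
  if (oh < 1 || ow < 1) stop("patch does not fit inside the (padded) map");
  arma::mat out(k * k * nc, (arma::uword)oh * ow, arma::fill::zeros);
  arma::uword col = 0;
  for (int cj = 0; cj < ow; ++cj) {
    for (int ci = 0; ci < oh; ++ci) {
      int r0 = ci * stride - pad_top;
      int c0 = cj * stride - pad_left;
      arma::uword idx = 0;
      for (int ch = 0; ch < nc; ++ch)
        for (int jj = 0; jj < k; ++jj)
          for (int ii = 0; ii < k; ++ii) {
            int r = r0 + ii, c = c0 + jj;
            out(idx++, col) =
              (r >= 0 && r < (int)x.n_rows && c >= 0 && c < (int)x.n_cols)
                ? x(r, c, ch) : 0.0;
          }
      ++col;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube maxpool_cpp(const arma::cube& x, int k, int stride) {
  const int oh = ((int)x.n_rows - k) / stride + 1;
  const int ow = ((int)x.n_cols - k) / stride + 1;
  if (oh < 1 || ow < 1) stop("pooling window does not fit inside the map");
  arma::cube out(oh, ow, x.n_slices);
  for (arma::uword ch = 0; ch < x.n_slices; ++ch)
    for (int cj = 0; cj < ow; ++cj)
      for (int ci = 0; ci < oh; ++ci) {
        double m = x(ci * stride, cj * stride, ch);
        for (int jj = 0; jj < k; ++jj)
          for (int ii = 0; ii < k; ++ii) {
            double v = x(ci * stride + ii, cj * stride + jj, ch);
            if (v > m) m = v;
          }
        out(ci, cj, ch) = m;
      }
  return out;
}

static void fisher_yates(std::vector<int>& p) {
  const int n = (int)p.size();
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p[i], p[j]);
  }
}

// Null distribution of the ranking distance: for each draw, two independent
// uniformly random permutations of 1..n, D = sum_i |log(i / f_Y(x_i))|.
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
NumericVector rd_null_sample_cpp(int n, int n_samples) {
  std::vector<int> x(n), y(n), pos(n);
  std::vector<double> lg(n);
  for (int i = 0; i < n; ++i) lg[i] = std::log((double)(i + 1));
  NumericVector out(n_samples);
  for (int s = 0; s < n_samples; ++s) {
    fisher_yates(x);
    fisher_yates(y);
    for (int i = 0; i < n; ++i) pos[y[i]] = i;
    double d = 0.0;
    for (int i = 0; i < n; ++i) d += std::abs(lg[i] - lg[pos[x[i]]]);
    out[s] = d;
  }
  return out;
}

// Per-unit randomization test on a units x pairs response layout. The
// per-pair index d = (cm - sm)/(cm + sm) changes sign when the CM and SM
// roles of a pair are swapped and its exclusion status does not, so the
// within-pair shuffle null is mean(+/- d) with independent fair signs.
// p = fraction of the null STRICTLY larger than the observed index.
// [[Rcpp::export]]
List unit_randomization_cpp(const arma::mat& cm, const arma::mat& sm,
                            int n_perm) {
  const arma::uword U = cm.n_rows, P = cm.n_cols;
  NumericVector pval(U), obs(U);
  IntegerVector nvalid(U);
  std::vector<double> d;
  d.reserve(P);
  for (arma::uword u = 0; u < U; ++u) {
    d.clear();
    for (arma::uword p = 0; p < P; ++p) {
      double a = cm(u, p), b = sm(u, p);
      if (a + b > 0.0) d.push_back((a - b) / (a + b));
    }
    nvalid[u] = (int)d.size();
    if (d.empty()) { pval[u] = NA_REAL; obs[u] = NA_REAL; continue; }
    double o = 0.0;
    for (double v : d) o += v;
    o /= d.size();
    obs[u] = o;
    int larger = 0;
    for (int r = 0; r < n_perm; ++r) {
      double s = 0.0;
      for (double v : d) s += (unif_rand() < 0.5) ? v : -v;
      if (s / d.size() > o) ++larger;
    }
    pval[u] = (double)larger / n_perm;
  }
  return List::create(_["observed"] = obs, _["p"] = pval,
                      _["n_valid"] = nvalid);
}
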