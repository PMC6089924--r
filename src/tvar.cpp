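// Compiled kernels for the TV-AR pipeline. Per-window work (autocorrelation,
// Levinson-Durbin, companion-matrix roots, residues) is O(nw*p + p^3) and is
// executed thousands of times per recording at 95% window overlap, so it
// lives here rather than in R.
#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Sliding-window Yule-Walker AR fit.
// x: signal; starts: 0-based window start indices; nw: window length;
// p: AR order. Windows are demeaned; the biased autocovariance estimator is
// used, which keeps every fitted polynomial minimum-phase (poles inside the
// unit circle). Returns coefficients a_k of 1 + sum_k a_k z^-k (p x W) and
// the innovation variance sigma2 (final Levinson prediction error).
// Autocovariances for all (heavily overlapping) windows are assembled from
// cumulative lagged products, O(N p) overall instead of O(W nw p).
// [[Rcpp::export]]
List cpp_sliding_yw(const arma::vec& x, const arma::uvec& starts, int nw, int p) {
  const int W = starts.n_elem;
  const int N = x.n_elem;
  arma::mat coeffs(p, W, arma::fill::zeros);
  arma::vec sigma2(W, arma::fill::zeros);
  arma::ivec ok(W, arma::fill::ones);

  // cumulative signal sum and per-lag cumulative products
  arma::vec cx(N + 1, arma::fill::zeros);
  for (int i = 0; i < N; ++i) cx(i + 1) = cx(i) + x(i);
  arma::mat R(p + 1, W);                  // demeaned biased autocovariances
  arma::vec cp(N + 1);
  for (int l = 0; l <= p; ++l) {
    cp.zeros();
    for (int i = l; i < N; ++i) cp(i + 1) = cp(i) + x(i) * x(i - l);
    for (int wi = 0; wi < W; ++wi) {
      const int s = starts(wi);
      double m = (cx(s + nw) - cx(s)) / nw;
      double raw = cp(s + nw) - cp(s + l);
      double sumA = cx(s + nw) - cx(s + l);        // x[t], t = s+l .. s+nw-1
      double sumB = cx(s + nw - l) - cx(s);        // x[t-l]
      R(l, wi) = (raw - m * sumA - m * sumB + (nw - l) * m * m) / nw;
    }
  }

  arma::vec r(p + 1);
  arma::vec phi(p), phi_prev(p);

  for (int wi = 0; wi < W; ++wi) {
    r = R.col(wi);
    if (r(0) <= 0.0 || !std::isfinite(r(0))) { ok(wi) = 0; continue; }

    // Levinson-Durbin
    double e = r(0);
    phi.zeros();
    for (int k = 1; k <= p; ++k) {
      double acc = r(k);
      for (int j = 1; j < k; ++j) acc -= phi(j - 1) * r(k - j);
      double kap = acc / e;
      phi_prev = phi;
      phi(k - 1) = kap;
      for (int j = 1; j < k; ++j) phi(j - 1) = phi_prev(j - 1) - kap * phi_prev(k - j - 1);
      e *= (1.0 - kap * kap);
      if (e <= 0.0) { e = std::max(e, 1e-300); }
    }
    // prediction form x_t = sum phi_j x_{t-j} + e_t  ->  a_k = -phi_k
    for (int k = 0; k < p; ++k) coeffs(k, wi) = -phi(k);
    sigma2(wi) = e;
  }
  return List::create(_["coeffs"] = coeffs, _["sigma2"] = sigma2, _["ok"] = ok);
}

// Roots of z^p + a1 z^{p-1} + ... + ap per window (columns of coeffs), as
// eigenvalues of the real companion matrix. The companion is already upper
// Hessenberg, so the QR eigenvalue iteration (dhseqr) is called directly.
// [[Rcpp::export]]
arma::cx_mat cpp_ar_roots(const arma::mat& coeffs) {
  const int p = coeffs.n_rows, W = coeffs.n_cols;
  arma::cx_mat roots(p, W, arma::fill::zeros);
  arma::mat H(p, p);
  arma::vec wr(p), wi_(p);
  int n = p, ilo = 1, ihi = p, ldh = p, ldz = 1, info = 0, lwork = -1;
  double zdum = 0.0, wkopt = 0.0;
  // workspace query
  F77_CALL(dhseqr)("E", "N", &n, &ilo, &ihi, H.memptr(), &ldh, wr.memptr(),
                   wi_.memptr(), &zdum, &ldz, &wkopt, &lwork, &info
                   FCONE FCONE);
  lwork = std::max(1, (int)wkopt);
  arma::vec work(lwork);
  for (int w = 0; w < W; ++w) {
    H.zeros();
    for (int k = 0; k < p; ++k) H(0, k) = -coeffs(k, w);
    for (int k = 1; k < p; ++k) H(k, k - 1) = 1.0;
    info = 0;
    F77_CALL(dhseqr)("E", "N", &n, &ilo, &ihi, H.memptr(), &ldh, wr.memptr(),
                     wi_.memptr(), &zdum, &ldz, work.memptr(), &lwork, &info
                     FCONE FCONE);
    if (info == 0) {
      for (int k = 0; k < p; ++k)
        roots(k, w) = arma::cx_double(wr(k), wi_(k));
    } else {
      roots.col(w).fill(arma::cx_double(arma::datum::nan, arma::datum::nan));
    }
  }
  return roots;
}

// Zero-phase IIR filtering: forward pass over the zero-padded signal, then
// a reverse pass, matching the usual filtfilt construction.
// [[Rcpp::export]]
arma::vec cpp_filtfilt(const arma::vec& b, const arma::vec& a,
                       const arma::vec& x) {
  const int n = x.n_elem;
  const int nb = b.n_elem, na = a.n_elem;
  const int pad = 2 * std::max(na, nb);
  const int m = n + pad;
  arma::vec bb = b / a(0), aa = a / a(0);
  arma::vec w(m, arma::fill::zeros), y(m, arma::fill::zeros);

  auto pass = [&](const arma::vec& in, arma::vec& out) {
    const int L = in.n_elem;
    for (int t = 0; t < L; ++t) {
      double acc = 0.0;
      for (int k = 0; k < nb && k <= t; ++k) acc += bb(k) * in(t - k);
      for (int k = 1; k < na && k <= t; ++k) acc -= aa(k) * out(t - k);
      out(t) = acc;
    }
  };
  arma::vec xin(m, arma::fill::zeros);
  xin.subvec(0, n - 1) = x;
  pass(xin, w);
  arma::vec wrv = arma::reverse(w);
  pass(wrv, y);
  arma::vec yr = arma::reverse(y);
  return yr.subvec(0, n - 1);
}

// Residues of H(z) = 1 / prod_k (1 - z_k z^-1) at each pole:
// r_k = 1 / prod_{j != k} (1 - z_j / z_k).  Near-coincident poles are
// perturbed by 1e-8 along their phase direction before the product.
// [[Rcpp::export]]
arma::cx_mat cpp_residues(const arma::cx_mat& poles) {
  const int p = poles.n_rows, W = poles.n_cols;
  arma::cx_mat res(p, W, arma::fill::zeros);
  arma::cx_vec z(p);
  for (int wi = 0; wi < W; ++wi) {
    z = poles.col(wi);
    // separate near-coincident poles
    for (int k = 1; k < p; ++k)
      for (int j = 0; j < k; ++j)
        if (std::abs(z(k) - z(j)) < 1e-8) {
          arma::cx_double dir = (std::abs(z(k)) > 0) ? z(k) / std::abs(z(k))
                                                     : arma::cx_double(1.0, 0.0);
          z(k) += 1e-8 * dir * double(j + 1);
        }
    for (int k = 0; k < p; ++k) {
      arma::cx_double prod(1.0, 0.0);
      bool bad = false;
      for (int j = 0; j < p; ++j) {
        if (j == k) continue;
        arma::cx_double term = 1.0 - z(j) / z(k);
        if (std::abs(term) < 1e-14) { bad = true; break; }
        prod *= term;
      }
      res(k, wi) = bad ? arma::cx_double(arma::datum::nan, 0.0) : 1.0 / prod;
    }
  }
  return res;
}

// Maximal-energy-pole selection: per window, the resonant frequency of the
// finite-power pole with maximal P_k among candidates (res_freqs non-NaN);
// ties within 1e-12 relative tolerance break toward the lower frequency.
// Windows without a candidate carry the previous value and are flagged.
// [[Rcpp::export]]
List cpp_mep_select(const arma::mat& res_freqs, const arma::mat& powers) {
  const int p = res_freqs.n_rows, W = res_freqs.n_cols;
  arma::vec vals(W); vals.fill(arma::datum::nan);
  arma::ivec flag(W, arma::fill::zeros);
  double prev = arma::datum::nan;
  for (int wi = 0; wi < W; ++wi) {
    double pmax = -arma::datum::inf;
    for (int k = 0; k < p; ++k)
      if (std::isfinite(res_freqs(k, wi)) && std::isfinite(powers(k, wi)) &&
          powers(k, wi) > pmax) pmax = powers(k, wi);
    if (!std::isfinite(pmax)) { vals(wi) = prev; flag(wi) = 1; continue; }
    double tol = 1e-12 * std::abs(pmax);
    double best = arma::datum::inf;
    for (int k = 0; k < p; ++k)
      if (std::isfinite(res_freqs(k, wi)) && std::isfinite(powers(k, wi)) &&
          powers(k, wi) >= pmax - tol && res_freqs(k, wi) < best)
        best = res_freqs(k, wi);
    vals(wi) = best;
    prev = best;
  }
  return List::create(_["values"] = vals, _["flagged"] = flag);
}

// Time-varying two-pole resonator driven by e:
//   y[n] = e[n] + 2 r[n] cos(2 pi f0[n]/fs) y[n-1] - r[n]^2 y[n-2]
// [[Rcpp::export]]
arma::vec cpp_tv_resonator(const arma::vec& e, const arma::vec& f0,
                           const arma::vec& r, double fs) {
  const int n = e.n_elem;
  arma::vec y(n, arma::fill::zeros);
  double y1 = 0.0, y2 = 0.0;
  const double w = 2.0 * M_PI / fs;
  for (int t = 0; t < n; ++t) {
    double b1 = 2.0 * r(t) * std::cos(w * f0(t));
    double b2 = -r(t) * r(t);
    double yt = e(t) + b1 * y1 + b2 * y2;
    y2 = y1; y1 = yt;
    y(t) = yt;
  }
  return y;
}
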