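// Selective state-space scan: per-token bilinear discretization of a shared
// diagonal continuous system A (length N), with token-dependent B, C
// (linear projections of the token) and a token-dependent step size
// delta = softplus(wd . x + bd).
//
// Layout: X is d x L (tokens in columns), hidden state H is d x N
// (one length-N state per channel). Per token n:
//   denom_j = 1 - delta/2 * a_j
//   Abar_j  = (1 + delta/2 * a_j) / denom_j
//   Bbar_j  = delta * B_j / denom_j
//   H[i,j] <- H[i,j] * Abar_j + x_i * Bbar_j
//   y_i     = sum_j H[i,j] * C_j
//
// The backward pass is plain reverse-mode through the recurrence; the full
// state trajectory is cached by the forward pass when gradients are needed.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double u) {
  return (u > 30.0) ? u : std::log1p(std::exp(u));
}
static inline double sigmoid(double u) {
  return 1.0 / (1.0 + std::exp(-u));
}

// [[Rcpp::export]]
List selscan_forward_cpp(NumericMatrix X, NumericMatrix Wb, NumericMatrix Wc,
                         NumericVector wd, double bd, NumericVector a,
                         bool want_cache) {
  const int d = X.nrow(), L = X.ncol(), N = a.size();
  NumericMatrix Y(d, L), Bm(N, L), Cm(N, L);
  NumericVector delta(L), u(L);
  NumericMatrix Hc(want_cache ? d * N : 1, want_cache ? L : 1);
  std::vector<double> H(d * N, 0.0), Ab(N), Bb(N);

  for (int n = 0; n < L; ++n) {
    double un = bd;
    for (int i = 0; i < d; ++i) un += wd[i] * X(i, n);
    if (!std::isfinite(un))
      stop("non-finite delta projection at token %d", n + 1);
    u[n] = un;
    const double dt = softplus(un);
    delta[n] = dt;
    for (int j = 0; j < N; ++j) {
      double bj = 0.0, cj = 0.0;
      for (int i = 0; i < d; ++i) {
        bj += Wb(j, i) * X(i, n);
        cj += Wc(j, i) * X(i, n);
      }
      if (!std::isfinite(bj) || !std::isfinite(cj))
        stop("non-finite B/C projection at token %d", n + 1);
      Bm(j, n) = bj;
      Cm(j, n) = cj;
      const double denom = 1.0 - 0.5 * dt * a[j];
      Ab[j] = (1.0 + 0.5 * dt * a[j]) / denom;
      Bb[j] = dt * bj / denom;
    }
    for (int j = 0; j < N; ++j) {
      const double abj = Ab[j], bbj = Bb[j];
      double* h = &H[(size_t)d * j];
      for (int i = 0; i < d; ++i) h[i] = h[i] * abj + X(i, n) * bbj;
    }
    for (int i = 0; i < d; ++i) {
      double yi = 0.0;
      for (int j = 0; j < N; ++j) yi += H[(size_t)d * j + i] * Cm(j, n);
      Y(i, n) = yi;
    }
    if (want_cache)
      for (int k = 0; k < d * N; ++k) Hc(k, n) = H[k];
  }
  return List::create(_["Y"] = Y, _["H"] = Hc, _["B"] = Bm, _["C"] = Cm,
                      _["delta"] = delta, _["u"] = u);
}

// [[Rcpp::export]]
List selscan_backward_cpp(NumericMatrix X, NumericMatrix Wb, NumericMatrix Wc,
                          NumericVector wd, NumericVector a,
                          NumericMatrix Hc, NumericMatrix Bm, NumericMatrix Cm,
                          NumericVector delta, NumericVector u,
                          NumericMatrix dY) {
  const int d = X.nrow(), L = X.ncol(), N = a.size();
  NumericMatrix dX(d, L), dWb(N, d), dWc(N, d);
  NumericVector dwd(d), da(N);
  double dbd = 0.0;
  std::vector<double> dH(d * N, 0.0), Ab(N), Bb(N), denom(N);
  std::vector<double> dB(N), dC(N), dAb(N), dBb(N);

  for (int n = L - 1; n >= 0; --n) {
    const double dt = delta[n];
    for (int j = 0; j < N; ++j) {
      denom[j] = 1.0 - 0.5 * dt * a[j];
      Ab[j] = (1.0 + 0.5 * dt * a[j]) / denom[j];
      Bb[j] = dt * Bm(j, n) / denom[j];
    }
    // y_n = H_n^T C_n per channel
    for (int j = 0; j < N; ++j) {
      double s = 0.0;
      const double* h = &Hc(0, n) + (size_t)d * j;
      for (int i = 0; i < d; ++i) s += h[i] * dY(i, n);
      dC[j] = s;
    }
    for (int j = 0; j < N; ++j) {
      double* dh = &dH[(size_t)d * j];
      const double c = Cm(j, n);
      for (int i = 0; i < d; ++i) dh[i] += dY(i, n) * c;
    }
    double ddt = 0.0;
    for (int j = 0; j < N; ++j) {
      double sA = 0.0, sB = 0.0;
      const double* dh = &dH[(size_t)d * j];
      for (int i = 0; i < d; ++i) {
        const double hprev = (n > 0) ? Hc((size_t)d * j + i, n - 1) : 0.0;
        sA += dh[i] * hprev;
        sB += dh[i] * X(i, n);
      }
      dAb[j] = sA;
      dBb[j] = sB;
      const double d2 = denom[j] * denom[j];
      ddt += sA * a[j] / d2 + sB * Bm(j, n) / d2;
      dB[j] = sB * dt / denom[j];
      da[j] += sA * dt / d2 + sB * 0.5 * dt * dt * Bm(j, n) / d2;
    }
    const double du = ddt * sigmoid(u[n]);
    dbd += du;
    for (int i = 0; i < d; ++i) {
      double dx = du * wd[i];
      for (int j = 0; j < N; ++j) {
        dx += dH[(size_t)d * j + i] * Bb[j];           // direct input term
        dx += Wb(j, i) * dB[j] + Wc(j, i) * dC[j];     // projection terms
      }
      dX(i, n) = dx;
      dwd[i] += du * X(i, n);
      for (int j = 0; j < N; ++j) {
        dWb(j, i) += dB[j] * X(i, n);
        dWc(j, i) += dC[j] * X(i, n);
      }
    }
    // propagate to H_{n-1}
    for (int j = 0; j < N; ++j) {
      double* dh = &dH[(size_t)d * j];
      for (int i = 0; i < d; ++i) dh[i] *= Ab[j];
    }
  }
  return List::create(_["dX"] = dX, _["dWb"] = dWb, _["dWc"] = dWc,
                      _["dwd"] = dwd, _["dbd"] = dbd, _["da"] = da);
}
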