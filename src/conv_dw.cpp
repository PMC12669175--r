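// Depthwise 3-D convolution (zero same-padding, stride 1; striding is a
// cheap subsample done by the caller).  Feature layout is (C, X, Y, Z),
// channel fastest; kernels have odd extents.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector conv_dw_full_cpp(NumericVector x, IntegerVector dims,
                               NumericVector W, IntegerVector kdims) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int kx = kdims[0], ky = kdims[1], kz = kdims[2];
  const int rx = kx / 2, ry = ky / 2, rz = kz / 2;
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const double* Wp = W.begin();           // (C, kx, ky, kz)
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        double* yo = yp + (size_t)C * (i + (size_t)X * (j + (size_t)Y * k));
        for (int tz = 0; tz < kz; ++tz) {
          const int sk = k + tz - rz;
          if (sk < 0 || sk >= Z) continue;
          for (int ty = 0; ty < ky; ++ty) {
            const int sj = j + ty - ry;
            if (sj < 0 || sj >= Y) continue;
            for (int tx = 0; tx < kx; ++tx) {
              const int si = i + tx - rx;
              if (si < 0 || si >= X) continue;
              const double* xo = xp + (size_t)C * (si + (size_t)X * (sj + (size_t)Y * sk));
              const double* wo = Wp + (size_t)C * (tx + (size_t)kx * (ty + (size_t)ky * tz));
              for (int c = 0; c < C; ++c) yo[c] += wo[c] * xo[c];
            }
          }
        }
      }
  y.attr("dim") = dims;
  return y;
}

// [[Rcpp::export]]
List conv_dw_bwd_cpp(NumericVector x, IntegerVector dims,
                     NumericVector W, IntegerVector kdims,
                     NumericVector dy) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int kx = kdims[0], ky = kdims[1], kz = kdims[2];
  const int rx = kx / 2, ry = ky / 2, rz = kz / 2;
  NumericVector dx(x.size()), dW(W.size());
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  const double* Wp = W.begin();
  double* dxp = dx.begin();
  double* dWp = dW.begin();
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const double* go = dyp + (size_t)C * (i + (size_t)X * (j + (size_t)Y * k));
        for (int tz = 0; tz < kz; ++tz) {
          const int sk = k + tz - rz;
          if (sk < 0 || sk >= Z) continue;
          for (int ty = 0; ty < ky; ++ty) {
            const int sj = j + ty - ry;
            if (sj < 0 || sj >= Y) continue;
            for (int tx = 0; tx < kx; ++tx) {
              const int si = i + tx - rx;
              if (si < 0 || si >= X) continue;
              const size_t so = (size_t)C * (si + (size_t)X * (sj + (size_t)Y * sk));
              const size_t wo = (size_t)C * (tx + (size_t)kx * (ty + (size_t)ky * tz));
              for (int c = 0; c < C; ++c) {
                dxp[so + c] += Wp[wo + c] * go[c];
                dWp[wo + c] += xp[so + c] * go[c];
              }
            }
          }
        }
      }
  dx.attr("dim") = dims;
  dW.attr("dim") = kdims.size() == 3
    ? IntegerVector::create(C, kx, ky, kz) : kdims;
  return List::create(_["dx"] = dx, _["dW"] = dW);
}
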