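#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are (H*W*T) x C column-major matrices; element (i + j*H) of
// frame t, channel c sits at [(i + j*H) + t*H*W + c*H*W*T]. Convolutions are
// same-padded k x k, accumulated tap by tap with implicit zero padding
// (bounds-limited loops), weights stored (k^2 * Cin) x Cout with rows
// channel-fastest within tap.

// [[Rcpp::export]]
NumericMatrix conv2d_fwd_cpp(const NumericMatrix& X, int H, int W, int TT,
                             int k, const NumericMatrix& Wmat,
                             const NumericVector& b) {
  const int Cin = X.ncol();
  const int Cout = Wmat.ncol();
  const int HW = H * W;
  const int n = HW * TT;
  const int p = (k - 1) / 2;
  NumericMatrix Y(n, Cout);
  const double* x = X.begin();
  double* y = Y.begin();
  for (int co = 0; co < Cout; ++co) {
    double bc = b[co];
    double* yc = y + (R_xlen_t)co * n;
    for (R_xlen_t q = 0; q < n; ++q) yc[q] = bc;
  }
  for (int co = 0; co < Cout; ++co) {
    double* yc = y + (R_xlen_t)co * n;
    for (int tap = 0; tap < k * k; ++tap) {
      const int di = tap % k, dj = tap / k;
      const int oi = di - p, oj = dj - p;
      const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
      const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
      for (int ci = 0; ci < Cin; ++ci) {
        const double w = Wmat(tap * Cin + ci, co);
        if (w == 0.0) continue;
        const double* xc = x + (R_xlen_t)ci * n;
        for (int t = 0; t < TT; ++t) {
          const R_xlen_t base = (R_xlen_t)t * HW;
          for (int j = j0; j < j1; ++j) {
            const double* xs = xc + base + (R_xlen_t)(j + oj) * H + oi;
            double* ys = yc + base + (R_xlen_t)j * H;
            for (int i = i0; i < i1; ++i) ys[i] += w * xs[i];
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const NumericMatrix& X, const NumericMatrix& dY,
                    int H, int W, int TT, int k, const NumericMatrix& Wmat) {
  const int Cin = X.ncol();
  const int Cout = Wmat.ncol();
  const int HW = H * W;
  const int n = HW * TT;
  const int p = (k - 1) / 2;
  NumericMatrix dX(n, Cin);
  NumericMatrix dW(Wmat.nrow(), Cout);
  NumericVector db(Cout);
  const double* x = X.begin();
  const double* dy = dY.begin();
  double* dx = dX.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* dyc = dy + (R_xlen_t)co * n;
    double acc = 0.0;
    for (R_xlen_t q = 0; q < n; ++q) acc += dyc[q];
    db[co] = acc;
    for (int tap = 0; tap < k * k; ++tap) {
      const int di = tap % k, dj = tap / k;
      const int oi = di - p, oj = dj - p;
      const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
      const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
      for (int ci = 0; ci < Cin; ++ci) {
        const double w = Wmat(tap * Cin + ci, co);
        const double* xc = x + (R_xlen_t)ci * n;
        double* dxc = dx + (R_xlen_t)ci * n;
        double gw = 0.0;
        for (int t = 0; t < TT; ++t) {
          const R_xlen_t base = (R_xlen_t)t * HW;
          for (int j = j0; j < j1; ++j) {
            const double* xs = xc + base + (R_xlen_t)(j + oj) * H + oi;
            double* dxs = dxc + base + (R_xlen_t)(j + oj) * H + oi;
            const double* dys = dyc + base + (R_xlen_t)j * H;
            for (int i = i0; i < i1; ++i) {
              gw += xs[i] * dys[i];
              dxs[i] += w * dys[i];
            }
          }
        }
        dW(tap * Cin + ci, co) = gw;
      }
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dW,
                      Named("db") = db);
}
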