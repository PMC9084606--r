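// Numerical kernels: trilinear volume resampling through a homogeneous
// matrix, and the 3D CNN primitives (3x3x3 same-padding convolution via
// im2col + GEMM, 2x2x2 ceil-mode max pooling, adaptive max pooling).
// Arrays follow R's column-major layout; feature maps are 5D (X,Y,Z,C,N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc5d(int X, int Y, int Z, int C, int N) {
  NumericVector v((R_xlen_t)X * Y * Z * C * N);
  v.attr("dim") = IntegerVector::create(X, Y, Z, C, N);
  return v;
}

static IntegerVector alloc5i(int X, int Y, int Z, int C, int N) {
  IntegerVector v((R_xlen_t)X * Y * Z * C * N);
  v.attr("dim") = IntegerVector::create(X, Y, Z, C, N);
  return v;
}

static void get_dims5(const NumericVector& x, int d[5]) {
  if (x.attr("dim") == R_NilValue) stop("expected a dim attribute");
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 5) stop("expected a 5D array");
  for (int i = 0; i < 5; ++i) d[i] = dim[i];
}

// ---------------------------------------------------------------------------
// Trilinear resampling: for each output voxel center (physical mm, origin at
// the volume center) apply M (4x4, output physical -> input physical) and
// sample the input volume trilinearly; out-of-field positions get `fill`.

// [[Rcpp::export]]
NumericVector resample_trilinear_cpp(NumericVector vol,
                                     NumericVector in_spacing,
                                     NumericMatrix M,
                                     IntegerVector out_shape,
                                     NumericVector out_spacing,
                                     double fill) {
  if (vol.attr("dim") == R_NilValue) stop("volume must be a 3D array");
  IntegerVector din = vol.attr("dim");
  if (din.size() != 3) stop("volume must be a 3D array");
  const int X = din[0], Y = din[1], Z = din[2];
  const int Xo = out_shape[0], Yo = out_shape[1], Zo = out_shape[2];
  if (M.nrow() != 4 || M.ncol() != 4) stop("M must be 4x4");

  NumericVector out(Rcpp::Dimension(Xo, Yo, Zo));
  const double* v = vol.begin();
  double* o = out.begin();

  const double cx_in = (X - 1) / 2.0, cy_in = (Y - 1) / 2.0,
               cz_in = (Z - 1) / 2.0;
  const double cx_o = (Xo - 1) / 2.0, cy_o = (Yo - 1) / 2.0,
               cz_o = (Zo - 1) / 2.0;

  for (int k = 0; k < Zo; ++k) {
    const double pz = (k - cz_o) * out_spacing[2];
    for (int j = 0; j < Yo; ++j) {
      const double py = (j - cy_o) * out_spacing[1];
      for (int i = 0; i < Xo; ++i) {
        const double px = (i - cx_o) * out_spacing[0];
        const double qx = M(0,0)*px + M(0,1)*py + M(0,2)*pz + M(0,3);
        const double qy = M(1,0)*px + M(1,1)*py + M(1,2)*pz + M(1,3);
        const double qz = M(2,0)*px + M(2,1)*py + M(2,2)*pz + M(2,3);
        // continuous voxel coordinates in the input grid
        const double fx = qx / in_spacing[0] + cx_in;
        const double fy = qy / in_spacing[1] + cy_in;
        const double fz = qz / in_spacing[2] + cz_in;
        double val = fill;
        if (fx >= 0 && fx <= X - 1 && fy >= 0 && fy <= Y - 1 &&
            fz >= 0 && fz <= Z - 1) {
          int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
              z0 = (int)std::floor(fz);
          if (x0 == X - 1) x0--;
          if (y0 == Y - 1) y0--;
          if (z0 == Z - 1) z0--;
          const double tx = fx - x0, ty = fy - y0, tz = fz - z0;
          const double* p000 = v + x0 + (size_t)X * (y0 + (size_t)Y * z0);
          const size_t sy = X, sz = (size_t)X * Y;
          const double c00 = p000[0]  * (1 - tx) + p000[1]  * tx;
          const double c10 = p000[sy] * (1 - tx) + p000[sy + 1] * tx;
          const double c01 = p000[sz] * (1 - tx) + p000[sz + 1] * tx;
          const double c11 = p000[sz + sy] * (1 - tx) + p000[sz + sy + 1] * tx;
          const double c0 = c00 * (1 - ty) + c10 * ty;
          const double c1 = c01 * (1 - ty) + c11 * ty;
          val = c0 * (1 - tz) + c1 * tz;
        }
        o[i + (size_t)Xo * (j + (size_t)Yo * k)] = val;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// im2col for a 3x3x3 kernel with same padding (pad 1, stride 1).
// K has 27*C rows (row = c*27 + (kz+1)*9 + (ky+1)*3 + (kx+1)) and X*Y*Z
// columns (column-major voxel order).

static void vol2col(const double* xs, int X, int Y, int Z, int C,
                    arma::mat& K) {
  const size_t V = (size_t)X * Y * Z;
  for (int c = 0; c < C; ++c) {
    const double* xc = xs + (size_t)c * V;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int row = c * 27 + (kz + 1) * 9 + (ky + 1) * 3 + (kx + 1);
          for (int z = 0; z < Z; ++z) {
            const int iz = z + kz;
            const bool zin = iz >= 0 && iz < Z;
            for (int y = 0; y < Y; ++y) {
              const int iy = y + ky;
              const bool yin = iy >= 0 && iy < Y;
              const size_t colbase = (size_t)X * (y + (size_t)Y * z);
              if (!zin || !yin) {
                for (int x = 0; x < X; ++x) K(row, colbase + x) = 0.0;
                continue;
              }
              const double* src = xc + (size_t)X * (iy + (size_t)Y * iz);
              for (int x = 0; x < X; ++x) {
                const int ix = x + kx;
                K(row, colbase + x) =
                    (ix >= 0 && ix < X) ? src[ix] : 0.0;
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, NumericMatrix W,
                                 NumericVector b) {
  int d[5]; get_dims5(x, d);
  const int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  const int Cout = W.nrow();
  if (W.ncol() != 27 * C) stop("weight shape mismatch");
  if (b.size() != Cout) stop("bias shape mismatch");
  const size_t V = (size_t)X * Y * Z;

  NumericVector y = alloc5d(X, Y, Z, Cout, N);
  arma::mat Wm(W.begin(), Cout, 27 * C, false);
  arma::mat K(27 * C, V);
  for (int n = 0; n < N; ++n) {
    vol2col(x.begin() + (size_t)n * V * C, X, Y, Z, C, K);
    arma::mat Ym = Wm * K;            // Cout x V
    double* ys = y.begin() + (size_t)n * V * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      double* yd = ys + (size_t)co * V;
      for (size_t v = 0; v < V; ++v) yd[v] = Ym(co, v) + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, NumericMatrix W, NumericVector dy) {
  int d[5]; get_dims5(x, d);
  const int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  const int Cout = W.nrow();
  const size_t V = (size_t)X * Y * Z;

  NumericVector dx = alloc5d(X, Y, Z, C, N);
  NumericMatrix dW(Cout, 27 * C);
  NumericVector db(Cout);
  arma::mat Wm(W.begin(), Cout, 27 * C, false);
  arma::mat dWm(dW.begin(), Cout, 27 * C, false);
  arma::vec dbv(db.begin(), Cout, false);
  arma::mat K(27 * C, V);
  arma::mat dY(Cout, V);

  for (int n = 0; n < N; ++n) {
    vol2col(x.begin() + (size_t)n * V * C, X, Y, Z, C, K);
    const double* dys = dy.begin() + (size_t)n * V * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* s = dys + (size_t)co * V;
      for (size_t v = 0; v < V; ++v) dY(co, v) = s[v];
    }
    dWm += dY * K.t();
    dbv += arma::sum(dY, 1);
    arma::mat dK = Wm.t() * dY;       // 27C x V
    // col2vol scatter-add
    double* dxs = dx.begin() + (size_t)n * V * C;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxs + (size_t)c * V;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            const int row = c * 27 + (kz + 1) * 9 + (ky + 1) * 3 + (kx + 1);
            for (int z = 0; z < Z; ++z) {
              const int iz = z + kz;
              if (iz < 0 || iz >= Z) continue;
              for (int y = 0; y < Y; ++y) {
                const int iy = y + ky;
                if (iy < 0 || iy >= Y) continue;
                const size_t colbase = (size_t)X * (y + (size_t)Y * z);
                double* dst = dxc + (size_t)X * (iy + (size_t)Y * iz);
                for (int xq = 0; xq < X; ++xq) {
                  const int ix = xq + kx;
                  if (ix < 0 || ix >= X) continue;
                  dst[ix] += dK(row, colbase + xq);
                }
              }
            }
          }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Max pooling. Window boundaries are precomputed per output index; the
// 2x2x2 ceil-mode pool and the adaptive pool share this implementation.
// The argmax (0-based linear voxel index within one channel's volume) is
// stored for the backward scatter.

static List maxpool_generic(const NumericVector& x,
                            const std::vector<int>& xs0, const std::vector<int>& xs1,
                            const std::vector<int>& ys0, const std::vector<int>& ys1,
                            const std::vector<int>& zs0, const std::vector<int>& zs1) {
  int d[5]; get_dims5(x, d);
  const int X = d[0], Y = d[1], Z = d[2], C = d[3], N = d[4];
  const int Xo = (int)xs0.size(), Yo = (int)ys0.size(), Zo = (int)zs0.size();
  const size_t V = (size_t)X * Y * Z, Vo = (size_t)Xo * Yo * Zo;

  NumericVector y = alloc5d(Xo, Yo, Zo, C, N);
  IntegerVector idx = alloc5i(Xo, Yo, Zo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * V;
      double* yc = y.begin() + (size_t)(n * C + c) * Vo;
      int* ic = idx.begin() + (size_t)(n * C + c) * Vo;
      for (int k = 0; k < Zo; ++k)
        for (int j = 0; j < Yo; ++j)
          for (int i = 0; i < Xo; ++i) {
            double best = -std::numeric_limits<double>::infinity();
            size_t besti = 0;
            for (int z = zs0[k]; z < zs1[k]; ++z)
              for (int yy = ys0[j]; yy < ys1[j]; ++yy)
                for (int xx = xs0[i]; xx < xs1[i]; ++xx) {
                  const size_t li = xx + (size_t)X * (yy + (size_t)Y * z);
                  if (xc[li] > best) { best = xc[li]; besti = li; }
                }
            const size_t lo = i + (size_t)Xo * (j + (size_t)Yo * k);
            yc[lo] = best;
            ic[lo] = (int)besti;
          }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

static void pool_bounds_fixed(int n, std::vector<int>& s0, std::vector<int>& s1) {
  const int no = (n + 1) / 2;            // ceil mode, kernel 2, stride 2
  s0.resize(no); s1.resize(no);
  for (int i = 0; i < no; ++i) {
    s0[i] = 2 * i;
    s1[i] = std::min(2 * i + 2, n);
  }
}

static void pool_bounds_adaptive(int n, int no, std::vector<int>& s0,
                                 std::vector<int>& s1) {
  s0.resize(no); s1.resize(no);
  for (int i = 0; i < no; ++i) {
    s0[i] = (int)std::floor((double)i * n / no);
    s1[i] = (int)std::ceil((double)(i + 1) * n / no);
  }
}

// [[Rcpp::export]]
List maxpool3d_forward_cpp(NumericVector x) {
  int d[5]; get_dims5(x, d);
  std::vector<int> xs0, xs1, ys0, ys1, zs0, zs1;
  pool_bounds_fixed(d[0], xs0, xs1);
  pool_bounds_fixed(d[1], ys0, ys1);
  pool_bounds_fixed(d[2], zs0, zs1);
  return maxpool_generic(x, xs0, xs1, ys0, ys1, zs0, zs1);
}

// [[Rcpp::export]]
List adaptive_maxpool3d_forward_cpp(NumericVector x, IntegerVector out_dim) {
  int d[5]; get_dims5(x, d);
  std::vector<int> xs0, xs1, ys0, ys1, zs0, zs1;
  pool_bounds_adaptive(d[0], out_dim[0], xs0, xs1);
  pool_bounds_adaptive(d[1], out_dim[1], ys0, ys1);
  pool_bounds_adaptive(d[2], out_dim[2], zs0, zs1);
  return maxpool_generic(x, xs0, xs1, ys0, ys1, zs0, zs1);
}

// [[Rcpp::export]]
NumericVector maxpool3d_backward_cpp(NumericVector dy, IntegerVector idx,
                                     IntegerVector in_dim) {
  int d[5]; get_dims5(dy, d);
  const int Xo = d[0], Yo = d[1], Zo = d[2], C = d[3], N = d[4];
  const int X = in_dim[0], Y = in_dim[1], Z = in_dim[2];
  const size_t V = (size_t)X * Y * Z, Vo = (size_t)Xo * Yo * Zo;
  NumericVector dx = alloc5d(X, Y, Z, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dyc = dy.begin() + (size_t)(n * C + c) * Vo;
      const int* ic = idx.begin() + (size_t)(n * C + c) * Vo;
      double* dxc = dx.begin() + (size_t)(n * C + c) * V;
      for (size_t v = 0; v < Vo; ++v) dxc[ic[v]] += dyc[v];
    }
  return dx;
}
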