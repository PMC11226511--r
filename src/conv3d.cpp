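#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Tensors are stored channel-fastest: an array with dim (C, D, H, W), so the
// linear index of voxel (c, z, y, x) is c + C*(z + D*(y + H*x)). Kernel taps
// are ordered t = tz + k*(ty + k*tx), matching the column-major flattening
// of a weight array with dim (Cout, Cin, k, k, k).

static inline int out_extent(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Direct dense 3-D convolution kernels. Weights are flat (Cout, Cin, k^3)
// arrays (tap t = tz + k*(ty + k*tx)); tensors are (C, D, H, W) channel
// fastest. Loops run tap-outer so both source and destination advance
// contiguously along the depth axis, and the per-voxel work is a small
// Cout x Cin product that vectorizes over the channel dimension.

// [[Rcpp::export(name = ".conv3d_direct")]]
NumericVector conv3d_direct(NumericVector x, NumericVector w, NumericVector b,
                            int Cin, int Cout, int D, int H, int W,
                            int k, int stride, int pad, int dil) {
  const int oD = out_extent(D, k, stride, pad, dil);
  const int oH = out_extent(H, k, stride, pad, dil);
  const int oW = out_extent(W, k, stride, pad, dil);
  NumericVector y((R_xlen_t)Cout * oD * oH * oW);
  double *py = y.begin();
  const double *px = x.begin();
  const double *pw = w.begin();
  for (R_xlen_t o = 0; o < (R_xlen_t)oD * oH * oW; ++o) {
    for (int c = 0; c < Cout; ++c) py[o * Cout + c] = b[c];
  }
  auto lohi = [&](int n, int toff, int on, int &lo, int &hi) {
    lo = 0;
    while (lo < on && lo * stride - pad + toff < 0) ++lo;
    hi = on - 1;
    while (hi >= 0 && hi * stride - pad + toff > n - 1) --hi;
  };
  const R_xlen_t cc = (R_xlen_t)Cout * Cin;
  for (int tx = 0; tx < k; ++tx) {
    int xlo, xhi; lohi(W, tx * dil, oW, xlo, xhi);
    for (int ty = 0; ty < k; ++ty) {
      int ylo, yhi; lohi(H, ty * dil, oH, ylo, yhi);
      for (int tz = 0; tz < k; ++tz) {
        int zlo, zhi; lohi(D, tz * dil, oD, zlo, zhi);
        const int t = tz + k * (ty + k * tx);
        const double *wt = pw + cc * t;  // (Cout x Cin) tap slice
        for (int ox = xlo; ox <= xhi; ++ox) {
          const int ix = ox * stride - pad + tx * dil;
          for (int oy = ylo; oy <= yhi; ++oy) {
            const int iy = oy * stride - pad + ty * dil;
            const int iz0 = zlo * stride - pad + tz * dil;
            const double *src = px + (R_xlen_t)Cin * (iz0 + D * (iy + H * ix));
            double *dst = py + (R_xlen_t)Cout * (zlo + oD * (oy + oH * ox));
            const R_xlen_t sstep = (R_xlen_t)Cin * stride;
            for (int oz = zlo; oz <= zhi; ++oz) {
              for (int ci = 0; ci < Cin; ++ci) {
                const double xv = src[ci];
                const double *wc = wt + (R_xlen_t)Cout * ci;
                for (int co = 0; co < Cout; ++co) dst[co] += wc[co] * xv;
              }
              src += sstep;
              dst += Cout;
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, oD, oH, oW);
  return y;
}

// Gradient wrt the input of .conv3d_direct.
// [[Rcpp::export(name = ".conv3d_direct_dx")]]
NumericVector conv3d_direct_dx(NumericVector dy, NumericVector w,
                               int Cin, int Cout, int D, int H, int W,
                               int k, int stride, int pad, int dil) {
  const int oD = out_extent(D, k, stride, pad, dil);
  const int oH = out_extent(H, k, stride, pad, dil);
  const int oW = out_extent(W, k, stride, pad, dil);
  NumericVector dx((R_xlen_t)Cin * D * H * W);
  double *pdx = dx.begin();
  const double *pdy = dy.begin();
  const double *pw = w.begin();
  auto lohi = [&](int n, int toff, int on, int &lo, int &hi) {
    lo = 0;
    while (lo < on && lo * stride - pad + toff < 0) ++lo;
    hi = on - 1;
    while (hi >= 0 && hi * stride - pad + toff > n - 1) --hi;
  };
  const R_xlen_t cc = (R_xlen_t)Cout * Cin;
  for (int tx = 0; tx < k; ++tx) {
    int xlo, xhi; lohi(W, tx * dil, oW, xlo, xhi);
    for (int ty = 0; ty < k; ++ty) {
      int ylo, yhi; lohi(H, ty * dil, oH, ylo, yhi);
      for (int tz = 0; tz < k; ++tz) {
        int zlo, zhi; lohi(D, tz * dil, oD, zlo, zhi);
        const int t = tz + k * (ty + k * tx);
        const double *wt = pw + cc * t;
        for (int ox = xlo; ox <= xhi; ++ox) {
          const int ix = ox * stride - pad + tx * dil;
          for (int oy = ylo; oy <= yhi; ++oy) {
            const int iy = oy * stride - pad + ty * dil;
            const int iz0 = zlo * stride - pad + tz * dil;
            double *dst = pdx + (R_xlen_t)Cin * (iz0 + D * (iy + H * ix));
            const double *src = pdy + (R_xlen_t)Cout * (zlo + oD * (oy + oH * ox));
            const R_xlen_t dstep = (R_xlen_t)Cin * stride;
            for (int oz = zlo; oz <= zhi; ++oz) {
              for (int ci = 0; ci < Cin; ++ci) {
                const double *wc = wt + (R_xlen_t)Cout * ci;
                double acc = 0.0;
                for (int co = 0; co < Cout; ++co) acc += wc[co] * src[co];
                dst[ci] += acc;
              }
              dst += dstep;
              src += Cout;
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(Cin, D, H, W);
  return dx;
}

// Gradient wrt the weights of .conv3d_direct; returns a (Cout, Cin, k^3) array.
// [[Rcpp::export(name = ".conv3d_direct_dw")]]
NumericVector conv3d_direct_dw(NumericVector x, NumericVector dy,
                               int Cin, int Cout, int D, int H, int W,
                               int k, int stride, int pad, int dil) {
  const int oD = out_extent(D, k, stride, pad, dil);
  const int oH = out_extent(H, k, stride, pad, dil);
  const int oW = out_extent(W, k, stride, pad, dil);
  NumericVector dw((R_xlen_t)Cout * Cin * k * k * k);
  double *pdw = dw.begin();
  const double *px = x.begin();
  const double *pdy = dy.begin();
  auto lohi = [&](int n, int toff, int on, int &lo, int &hi) {
    lo = 0;
    while (lo < on && lo * stride - pad + toff < 0) ++lo;
    hi = on - 1;
    while (hi >= 0 && hi * stride - pad + toff > n - 1) --hi;
  };
  const R_xlen_t cc = (R_xlen_t)Cout * Cin;
  for (int tx = 0; tx < k; ++tx) {
    int xlo, xhi; lohi(W, tx * dil, oW, xlo, xhi);
    for (int ty = 0; ty < k; ++ty) {
      int ylo, yhi; lohi(H, ty * dil, oH, ylo, yhi);
      for (int tz = 0; tz < k; ++tz) {
        int zlo, zhi; lohi(D, tz * dil, oD, zlo, zhi);
        const int t = tz + k * (ty + k * tx);
        double *dwt = pdw + cc * t;
        for (int ox = xlo; ox <= xhi; ++ox) {
          const int ix = ox * stride - pad + tx * dil;
          for (int oy = ylo; oy <= yhi; ++oy) {
            const int iy = oy * stride - pad + ty * dil;
            const int iz0 = zlo * stride - pad + tz * dil;
            const double *sx = px + (R_xlen_t)Cin * (iz0 + D * (iy + H * ix));
            const double *sy = pdy + (R_xlen_t)Cout * (zlo + oD * (oy + oH * ox));
            const R_xlen_t sstep = (R_xlen_t)Cin * stride;
            for (int oz = zlo; oz <= zhi; ++oz) {
              for (int ci = 0; ci < Cin; ++ci) {
                const double xv = sx[ci];
                double *wc = dwt + (R_xlen_t)Cout * ci;
                for (int co = 0; co < Cout; ++co) wc[co] += sy[co] * xv;
              }
              sx += sstep;
              sy += Cout;
            }
          }
        }
      }
    }
  }
  dw.attr("dim") = IntegerVector::create(Cout, Cin, k * k * k);
  return dw;
}

// Depthwise (per-channel) convolution, stride 1, zero "same" padding.
// w is a (C x k^3) matrix with tap order tz + k*(ty + k*tx).
// [[Rcpp::export(name = ".dwconv3d")]]
NumericVector dwconv3d(NumericVector x, NumericMatrix w, NumericVector b,
                       int C, int D, int H, int W, int k, int dil, int pad) {
  NumericVector y((R_xlen_t)C * D * H * W);
  const double *px = x.begin();
  const double *pw = w.begin();
  double *py = y.begin();
  for (int ox = 0; ox < W; ++ox) {
    for (int oy = 0; oy < H; ++oy) {
      for (int oz = 0; oz < D; ++oz) {
        double *dst = py + (R_xlen_t)C * (oz + D * (oy + H * ox));
        for (int c = 0; c < C; ++c) dst[c] = b[c];
        for (int tx = 0; tx < k; ++tx) {
          const int ix = ox - pad + tx * dil;
          if (ix < 0 || ix >= W) continue;
          for (int ty = 0; ty < k; ++ty) {
            const int iy = oy - pad + ty * dil;
            if (iy < 0 || iy >= H) continue;
            for (int tz = 0; tz < k; ++tz) {
              const int iz = oz - pad + tz * dil;
              if (iz < 0 || iz >= D) continue;
              const int t = tz + k * (ty + k * tx);
              const double *src = px + (R_xlen_t)C * (iz + D * (iy + H * ix));
              const double *wt = pw + (R_xlen_t)C * t;
              for (int c = 0; c < C; ++c) dst[c] += src[c] * wt[c];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, D, H, W);
  return y;
}

// Gradient of dwconv3d wrt its input (correlation adjoint).
// [[Rcpp::export(name = ".dwconv3d_bwd_dx")]]
NumericVector dwconv3d_bwd_dx(NumericVector dy, NumericMatrix w,
                              int C, int D, int H, int W, int k, int dil, int pad) {
  NumericVector dx((R_xlen_t)C * D * H * W);
  const double *pdy = dy.begin();
  const double *pw = w.begin();
  double *pdx = dx.begin();
  for (int ox = 0; ox < W; ++ox) {
    for (int oy = 0; oy < H; ++oy) {
      for (int oz = 0; oz < D; ++oz) {
        const double *g = pdy + (R_xlen_t)C * (oz + D * (oy + H * ox));
        for (int tx = 0; tx < k; ++tx) {
          const int ix = ox - pad + tx * dil;
          if (ix < 0 || ix >= W) continue;
          for (int ty = 0; ty < k; ++ty) {
            const int iy = oy - pad + ty * dil;
            if (iy < 0 || iy >= H) continue;
            for (int tz = 0; tz < k; ++tz) {
              const int iz = oz - pad + tz * dil;
              if (iz < 0 || iz >= D) continue;
              const int t = tz + k * (ty + k * tx);
              double *dst = pdx + (R_xlen_t)C * (iz + D * (iy + H * ix));
              const double *wt = pw + (R_xlen_t)C * t;
              for (int c = 0; c < C; ++c) dst[c] += g[c] * wt[c];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, D, H, W);
  return dx;
}

// Gradient of dwconv3d wrt its weights.
// [[Rcpp::export(name = ".dwconv3d_bwd_dw")]]
NumericMatrix dwconv3d_bwd_dw(NumericVector x, NumericVector dy,
                              int C, int D, int H, int W, int k, int dil, int pad) {
  NumericMatrix dw(C, k * k * k);
  const double *px = x.begin();
  const double *pdy = dy.begin();
  double *pdw = dw.begin();
  for (int ox = 0; ox < W; ++ox) {
    for (int oy = 0; oy < H; ++oy) {
      for (int oz = 0; oz < D; ++oz) {
        const double *g = pdy + (R_xlen_t)C * (oz + D * (oy + H * ox));
        for (int tx = 0; tx < k; ++tx) {
          const int ix = ox - pad + tx * dil;
          if (ix < 0 || ix >= W) continue;
          for (int ty = 0; ty < k; ++ty) {
            const int iy = oy - pad + ty * dil;
            if (iy < 0 || iy >= H) continue;
            for (int tz = 0; tz < k; ++tz) {
              const int iz = oz - pad + tz * dil;
              if (iz < 0 || iz >= D) continue;
              const int t = tz + k * (ty + k * tx);
              const double *src = px + (R_xlen_t)C * (iz + D * (iy + H * ix));
              double *dst = pdw + (R_xlen_t)C * t;
              for (int c = 0; c < C; ++c) dst[c] += g[c] * src[c];
            }
          }
        }
      }
    }
  }
  return dw;
}

// Leaky ReLU forward and input-gradient, single pass.
// [[Rcpp::export(name = ".lrelu")]]
NumericVector lrelu_cpp(NumericVector x, double slope) {
  NumericVector y(x.size());
  const double *px = x.begin();
  double *py = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    py[i] = px[i] > 0 ? px[i] : slope * px[i];
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".lrelu_bwd")]]
NumericVector lrelu_bwd_cpp(NumericVector x, NumericVector dy, double slope) {
  NumericVector dx(x.size());
  const double *px = x.begin();
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    pdx[i] = px[i] > 0 ? pdy[i] : slope * pdy[i];
  }
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// Separable 1-D convolution of a (D, H, W) volume along one axis
// (1 = depth, 2 = height, 3 = width) with replicate (edge-clamp) padding,
// so constant volumes are preserved exactly for normalized kernels.
// [[Rcpp::export(name = ".conv1d_axis")]]
NumericVector conv1d_axis(NumericVector x, int D, int H, int W,
                          NumericVector kern, int axis) {
  const int kl = kern.size();
  const int r = (kl - 1) / 2;
  NumericVector y((R_xlen_t)D * H * W);
  const double *px = x.begin();
  double *py = y.begin();
  const int n = (axis == 1) ? D : (axis == 2) ? H : W;
  for (int xw = 0; xw < W; ++xw) {
    for (int yh = 0; yh < H; ++yh) {
      for (int zd = 0; zd < D; ++zd) {
        double acc = 0.0;
        for (int t = 0; t < kl; ++t) {
          int p = ((axis == 1) ? zd : (axis == 2) ? yh : xw) + t - r;
          if (p < 0) p = 0;
          if (p >= n) p = n - 1;
          int iz = zd, iy = yh, ix = xw;
          if (axis == 1) iz = p; else if (axis == 2) iy = p; else ix = p;
          acc += kern[t] * px[iz + (R_xlen_t)D * (iy + H * ix)];
        }
        py[zd + (R_xlen_t)D * (yh + H * xw)] = acc;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(D, H, W);
  return y;
}

// Trilinear sampling of a (D, H, W) volume at fractional voxel coordinates
// (0-based). Out-of-range coordinates either clamp to the edge or read a
// constant fill value.
// [[Rcpp::export(name = ".trilinear_sample")]]
NumericVector trilinear_sample(NumericVector src, int D, int H, int W,
                               NumericVector zc, NumericVector yc, NumericVector xc,
                               bool clamp, double fill) {
  const R_xlen_t n = zc.size();
  NumericVector out(n);
  const double *p = src.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double z = zc[i], y = yc[i], x = xc[i];
    if (!clamp && (z < 0 || z > D - 1 || y < 0 || y > H - 1 || x < 0 || x > W - 1)) {
      out[i] = fill;
      continue;
    }
    if (z < 0) z = 0; if (z > D - 1) z = D - 1;
    if (y < 0) y = 0; if (y > H - 1) y = H - 1;
    if (x < 0) x = 0; if (x > W - 1) x = W - 1;
    const int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
    const int z1 = std::min(z0 + 1, D - 1), y1 = std::min(y0 + 1, H - 1),
              x1 = std::min(x0 + 1, W - 1);
    const double fz = z - z0, fy = y - y0, fx = x - x0;
    double v = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
      const int zz = dz ? z1 : z0;
      const double wz = dz ? fz : 1 - fz;
      for (int dy = 0; dy <= 1; ++dy) {
        const int yy = dy ? y1 : y0;
        const double wy = dy ? fy : 1 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          const int xx = dx ? x1 : x0;
          const double wx = dx ? fx : 1 - fx;
          v += wz * wy * wx * p[zz + (R_xlen_t)D * (yy + H * xx)];
        }
      }
    }
    out[i] = v;
  }
  return out;
}

// Nearest-neighbour sampling (for label volumes), same conventions.
// [[Rcpp::export(name = ".nearest_sample")]]
NumericVector nearest_sample(NumericVector src, int D, int H, int W,
                             NumericVector zc, NumericVector yc, NumericVector xc,
                             bool clamp, double fill) {
  const R_xlen_t n = zc.size();
  NumericVector out(n);
  const double *p = src.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double z = zc[i], y = yc[i], x = xc[i];
    if (!clamp && (z < -0.5 || z > D - 0.5 || y < -0.5 || y > H - 0.5 ||
                   x < -0.5 || x > W - 0.5)) {
      out[i] = fill;
      continue;
    }
    int zi = (int)std::lround(z), yi = (int)std::lround(y), xi = (int)std::lround(x);
    if (zi < 0) zi = 0; if (zi >= D) zi = D - 1;
    if (yi < 0) yi = 0; if (yi >= H) yi = H - 1;
    if (xi < 0) xi = 0; if (xi >= W) xi = W - 1;
    out[i] = p[zi + (R_xlen_t)D * (yi + H * xi)];
  }
  return out;
}

// For each point in a (n x 3) matrix, the minimum Euclidean distance to any
// point of a (m x 3) matrix. Coordinates are expected in physical units (mm).
// [[Rcpp::export(name = ".min_dist_to_set")]]
NumericVector min_dist_to_set(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double az = a(i, 0), ay = a(i, 1), ax = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dz = az - b(j, 0), dy = ay - b(j, 1), dx = ax - b(j, 2);
      const double d2 = dz * dz + dy * dy + dx * dx;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
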