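#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Feature maps are R arrays in column-major order:
//   2D: dim c(C, H, W), element (c,h,w) at c + C*(h + H*w)
//   3D: dim c(C, D, H, W), element (c,d,h,w) at c + C*(d + D*(h + H*w))
// im2col produces a K x N matrix (K = C*prod(kernel), N = spatial size) so a
// convolution is a single BLAS matmul in R. Stride is always 1; spatial
// down/upsampling is done by pooling / nearest upsampling layers.

// [[Rcpp::export]]
NumericMatrix im2col2d_cpp(NumericVector x, int C, int H, int W,
                           int kh, int kw, int dil) {
  const int padh = dil * (kh - 1) / 2, padw = dil * (kw - 1) / 2;
  const int K = C * kh * kw, N = H * W;
  NumericMatrix col(K, N);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const int n = h + H * w;
      for (int kj = 0; kj < kw; ++kj) {
        const int ww = w + dil * kj - padw;
        for (int ki = 0; ki < kh; ++ki) {
          const int hh = h + dil * ki - padh;
          const int rbase = C * (ki + kh * kj);
          if (hh >= 0 && hh < H && ww >= 0 && ww < W) {
            const int xbase = C * (hh + H * ww);
            for (int c = 0; c < C; ++c)
              col(rbase + c, n) = x[xbase + c];
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector col2im2d_cpp(NumericMatrix col, int C, int H, int W,
                           int kh, int kw, int dil) {
  const int padh = dil * (kh - 1) / 2, padw = dil * (kw - 1) / 2;
  NumericVector x(C * H * W);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      const int n = h + H * w;
      for (int kj = 0; kj < kw; ++kj) {
        const int ww = w + dil * kj - padw;
        for (int ki = 0; ki < kh; ++ki) {
          const int hh = h + dil * ki - padh;
          const int rbase = C * (ki + kh * kj);
          if (hh >= 0 && hh < H && ww >= 0 && ww < W) {
            const int xbase = C * (hh + H * ww);
            for (int c = 0; c < C; ++c)
              x[xbase + c] += col(rbase + c, n);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
NumericMatrix im2col3d_cpp(NumericVector x, int C, int D, int H, int W,
                           int kd, int kh, int kw) {
  const int padd = (kd - 1) / 2, padh = (kh - 1) / 2, padw = (kw - 1) / 2;
  const int K = C * kd * kh * kw, N = D * H * W;
  NumericMatrix col(K, N);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const int n = d + D * (h + H * w);
        for (int kj = 0; kj < kw; ++kj) {
          const int ww = w + kj - padw;
          if (ww < 0 || ww >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hh = h + ki - padh;
            if (hh < 0 || hh >= H) continue;
            for (int kk = 0; kk < kd; ++kk) {
              const int dd = d + kk - padd;
              if (dd < 0 || dd >= D) continue;
              const int rbase = C * (kk + kd * (ki + kh * kj));
              const int xbase = C * (dd + D * (hh + H * ww));
              for (int c = 0; c < C; ++c)
                col(rbase + c, n) = x[xbase + c];
            }
          }
        }
      }
  return col;
}

// [[Rcpp::export]]
NumericVector col2im3d_cpp(NumericMatrix col, int C, int D, int H, int W,
                           int kd, int kh, int kw) {
  const int padd = (kd - 1) / 2, padh = (kh - 1) / 2, padw = (kw - 1) / 2;
  NumericVector x(C * D * H * W);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const int n = d + D * (h + H * w);
        for (int kj = 0; kj < kw; ++kj) {
          const int ww = w + kj - padw;
          if (ww < 0 || ww >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hh = h + ki - padh;
            if (hh < 0 || hh >= H) continue;
            for (int kk = 0; kk < kd; ++kk) {
              const int dd = d + kk - padd;
              if (dd < 0 || dd >= D) continue;
              const int rbase = C * (kk + kd * (ki + kh * kj));
              const int xbase = C * (dd + D * (hh + H * ww));
              for (int c = 0; c < C; ++c)
                x[xbase + c] += col(rbase + c, n);
            }
          }
        }
      }
  return x;
}

// 2x2 (2D) / 2x2x2 (3D) max pooling with argmax indices for the backward pass.
// [[Rcpp::export]]
List maxpool2d_cpp(NumericVector x, int C, int H, int W) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(C * Ho * Wo);
  IntegerVector idx(C * Ho * Wo);
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h)
      for (int c = 0; c < C; ++c) {
        double best = -std::numeric_limits<double>::infinity();
        int besti = -1;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const int i = c + C * ((2 * h + dh) + H * (2 * w + dw));
            if (x[i] > best) { best = x[i]; besti = i; }
          }
        const int o = c + C * (h + Ho * w);
        out[o] = best; idx[o] = besti;
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
List maxpool3d_cpp(NumericVector x, int C, int D, int H, int W) {
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector out(C * Do * Ho * Wo);
  IntegerVector idx(C * Do * Ho * Wo);
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h)
      for (int d = 0; d < Do; ++d)
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              for (int dd = 0; dd < 2; ++dd) {
                const int i = c + C * ((2 * d + dd) + D * ((2 * h + dh) + H * (2 * w + dw)));
                if (x[i] > best) { best = x[i]; besti = i; }
              }
          const int o = c + C * (d + Do * (h + Ho * w));
          out[o] = best; idx[o] = besti;
        }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher):
// for every pixel, squared distance to the nearest site (sites = nonzero
// entries). Returns a large sentinel when there are no sites.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(IntegerMatrix sites) {
  const int H = sites.nrow(), W = sites.ncol();
  const double INF = 1e20;
  NumericMatrix d(H, W);
  std::vector<double> f(std::max(H, W)), tmp(std::max(H, W));
  // columns first
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = sites(i, j) ? 0.0 : INF;
    dt1d(f, tmp, H);
    for (int i = 0; i < H; ++i) d(i, j) = tmp[i];
  }
  // then rows
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = d(i, j);
    dt1d(f, tmp, W);
    for (int j = 0; j < W; ++j) d(i, j) = tmp[j];
  }
  return d;
}

// Connected-component labels, 8-connectivity, column-major scan order so the
// first component encountered gets label 1.
// [[Rcpp::export]]
IntegerMatrix label2d_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}

// 26-connectivity labels for a D x H x W volume (column-major vector in, out).
// [[Rcpp::export]]
IntegerVector label3d_cpp(IntegerVector mask, int D, int H, int W) {
  IntegerVector lab(D * H * W);
  int next = 0;
  std::queue<int> q;
  const int n = D * H * W;
  for (int v = 0; v < n; ++v) {
    if (!mask[v] || lab[v]) continue;
    lab[v] = ++next;
    q.push(v);
    while (!q.empty()) {
      const int p = q.front(); q.pop();
      const int d = p % D, h = (p / D) % H, w = p / (D * H);
      for (int dw = -1; dw <= 1; ++dw)
        for (int dh = -1; dh <= 1; ++dh)
          for (int dd = -1; dd <= 1; ++dd) {
            const int d2 = d + dd, h2 = h + dh, w2 = w + dw;
            if (d2 < 0 || d2 >= D || h2 < 0 || h2 >= H || w2 < 0 || w2 >= W) continue;
            const int p2 = d2 + D * (h2 + H * w2);
            if (mask[p2] && !lab[p2]) { lab[p2] = next; q.push(p2); }
          }
    }
  }
  return lab;
}

// Fused direct 3D convolution (stride 1, same padding); avoids the large
// im2col intermediate. Weight matrix rows follow the im2col row order
// r = c + C*(kk + kd*(ki + kh*kj)).
// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericMatrix Wm,
                             NumericVector b, int C, int D, int H, int W,
                             int k) {
  const int pad = (k - 1) / 2;
  const int Cout = Wm.nrow();
  NumericVector y(Cout * D * H * W);
  const double* xp = x.begin();
  const double* wp = Wm.begin();   // column-major: wp[co + Cout*r]
  const double* bp = b.begin();
  double* yp = y.begin();
  std::vector<double> acc(Cout);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const int n = d + D * (h + H * w);
        for (int co = 0; co < Cout; ++co) acc[co] = bp[co];
        for (int kj = 0; kj < k; ++kj) {
          const int ww = w + kj - pad;
          if (ww < 0 || ww >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int hh = h + ki - pad;
            if (hh < 0 || hh >= H) continue;
            for (int kk = 0; kk < k; ++kk) {
              const int dd = d + kk - pad;
              if (dd < 0 || dd >= D) continue;
              const int rbase = C * (kk + k * (ki + k * kj));
              const double* xv = xp + C * (dd + D * (hh + H * ww));
              const double* wc = wp + (size_t)Cout * rbase;
              for (int c = 0; c < C; ++c) {
                const double xvc = xv[c];
                for (int co = 0; co < Cout; ++co)
                  acc[co] += wc[co] * xvc;
                wc += Cout;
              }
            }
          }
        }
        double* yn = yp + (size_t)Cout * n;
        for (int co = 0; co < Cout; ++co) yn[co] = acc[co];
      }
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericMatrix Wm, NumericVector g,
                    int C, int D, int H, int W, int k) {
  const int pad = (k - 1) / 2;
  const int Cout = Wm.nrow(), K = Wm.ncol();
  NumericVector dx(C * D * H * W), db(Cout);
  NumericMatrix dW(Cout, K);
  const double* xp = x.begin();
  const double* wp = Wm.begin();
  const double* gp = g.begin();
  double* dxp = dx.begin();
  double* dwp = dW.begin();
  double* dbp = db.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const int n = d + D * (h + H * w);
        const double* gn = gp + (size_t)Cout * n;
        for (int co = 0; co < Cout; ++co) dbp[co] += gn[co];
        for (int kj = 0; kj < k; ++kj) {
          const int ww = w + kj - pad;
          if (ww < 0 || ww >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int hh = h + ki - pad;
            if (hh < 0 || hh >= H) continue;
            for (int kk = 0; kk < k; ++kk) {
              const int dd = d + kk - pad;
              if (dd < 0 || dd >= D) continue;
              const int rbase = C * (kk + k * (ki + k * kj));
              const size_t xbase = C * (dd + D * (hh + H * ww));
              const double* wc = wp + (size_t)Cout * rbase;
              double* dwc = dwp + (size_t)Cout * rbase;
              for (int c = 0; c < C; ++c) {
                const double xvc = xp[xbase + c];
                double dxa = 0.0;
                for (int co = 0; co < Cout; ++co) {
                  dwc[co] += gn[co] * xvc;
                  dxa += wc[co] * gn[co];
                }
                dxp[xbase + c] += dxa;
                wc += Cout; dwc += Cout;
              }
            }
          }
        }
      }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
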