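#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// reflect-101 index: mirror about the border pixel itself (-1 -> 1,
// n -> n-2), the padding convention of all windowed operators here.
static inline int reflect101(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static inline int round_half_up(double x) {
  return (int)std::floor(x + 0.5);
}

// copy into an (h+2r) x (w+2r) column-major buffer with reflect-101 borders
static std::vector<int> pad101(const IntegerMatrix& img, int r) {
  const int h = img.nrow(), w = img.ncol();
  const int ph = h + 2 * r, pw = w + 2 * r;
  std::vector<int> buf((size_t)ph * pw);
  for (int j = 0; j < pw; ++j) {
    const int sj = reflect101(j - r, w);
    const int* col = &img[0] + (size_t)sj * h;
    int* out = buf.data() + (size_t)j * ph;
    for (int i = 0; i < ph; ++i) out[i] = col[reflect101(i - r, h)];
  }
  return buf;
}

static inline void cswap(int& a, int& b) {
  if (b < a) { const int t = a; a = b; b = t; }
}

// median of 9 via a fixed comparison network (no full sort)
static inline int median9(int p0, int p1, int p2, int p3, int p4,
                          int p5, int p6, int p7, int p8) {
  cswap(p1, p2); cswap(p4, p5); cswap(p7, p8);
  cswap(p0, p1); cswap(p3, p4); cswap(p6, p7);
  cswap(p1, p2); cswap(p4, p5); cswap(p7, p8);
  cswap(p0, p3); cswap(p5, p8); cswap(p4, p7);
  cswap(p3, p6); cswap(p1, p4); cswap(p2, p5);
  cswap(p4, p7); cswap(p4, p2); cswap(p6, p4);
  cswap(p4, p2);
  return p4;
}

// [[Rcpp::export(name = ".median_filter_cpp")]]
IntegerMatrix median_filter_cpp(const IntegerMatrix& img, int kernel) {
  const int h = img.nrow(), w = img.ncol(), r = kernel / 2;
  const int ph = h + 2 * r;
  const int win = kernel * kernel, mid = win / 2;
  std::vector<int> pad = pad101(img, r);
  IntegerMatrix out(h, w);
  if (kernel == 3) {
    for (int j = 0; j < w; ++j) {
      const int* c0 = pad.data() + (size_t)j * ph;
      const int* c1 = c0 + ph;
      const int* c2 = c1 + ph;
      for (int i = 0; i < h; ++i)
        out(i, j) = median9(c0[i], c0[i + 1], c0[i + 2],
                            c1[i], c1[i + 1], c1[i + 2],
                            c2[i], c2[i + 1], c2[i + 2]);
    }
    return out;
  }
  std::vector<int> v(win);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int k = 0;
      for (int dj = 0; dj < kernel; ++dj) {
        const int* col = pad.data() + (size_t)(j + dj) * ph + i;
        for (int di = 0; di < kernel; ++di) v[k++] = col[di];
      }
      std::nth_element(v.begin(), v.begin() + mid, v.end());
      out(i, j) = v[mid];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".bilateral_filter_cpp")]]
IntegerMatrix bilateral_filter_cpp(const IntegerMatrix& img, int diameter,
                                   double sigma_color, double sigma_space) {
  const int h = img.nrow(), w = img.ncol(), r = diameter / 2;
  const int ph = h + 2 * r, side = 2 * r + 1;
  std::vector<int> pad = pad101(img, r);
  IntegerMatrix out(h, w);
  std::vector<double> ws((size_t)side * side);
  for (int dj = 0; dj < side; ++dj)
    for (int di = 0; di < side; ++di)
      ws[(size_t)dj * side + di] = std::exp(
        -(double)((di - r) * (di - r) + (dj - r) * (dj - r)) /
        (2.0 * sigma_space * sigma_space));
  double wc[511];  // LUT over intensity difference + 255
  for (int v = -255; v <= 255; ++v)
    wc[v + 255] = std::exp(-(double)(v * v) /
                           (2.0 * sigma_color * sigma_color));
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      const int c = pad[(size_t)(j + r) * ph + (i + r)];
      double num = 0.0, den = 0.0;
      for (int dj = 0; dj < side; ++dj) {
        const int* col = pad.data() + (size_t)(j + dj) * ph + i;
        const double* wrow = ws.data() + (size_t)dj * side;
        for (int di = 0; di < side; ++di) {
          const int v = col[di];
          const double wgt = wrow[di] * wc[v - c + 255];
          num += wgt * v;
          den += wgt;
        }
      }
      out(i, j) = round_half_up(num / den);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".sobel_cpp")]]
List sobel_cpp(const IntegerMatrix& img) {
  const int h = img.nrow(), w = img.ncol();
  const int ph = h + 2;
  std::vector<int> pad = pad101(img, 1);
  // cross-correlation kernels; kx = [[-1,0,1],[-2,0,2],[-1,0,1]], ky = t(kx)
  IntegerMatrix gx(h, w), gy(h, w);
  for (int j = 0; j < w; ++j) {
    const int* c0 = pad.data() + (size_t)j * ph;
    const int* c1 = c0 + ph;
    const int* c2 = c1 + ph;
    for (int i = 0; i < h; ++i) {
      const int a = c0[i], b = c0[i + 1], c = c0[i + 2];
      const int d = c1[i], f = c1[i + 2];
      const int g = c2[i], p = c2[i + 1], q = c2[i + 2];
      gx(i, j) = (g + 2 * p + q) - (a + 2 * b + c);
      gy(i, j) = (c + 2 * f + q) - (a + 2 * d + g);
    }
  }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}
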