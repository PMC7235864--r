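#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// squared Euclidean distance between row-major vectors a and b of length d
static inline double sqdist(const double* a, const double* b, int d) {
  double s = 0.0;
  for (int j = 0; j < d; ++j) {
    const double diff = a[j] - b[j];
    s += diff * diff;
  }
  return s;
}

// Lloyd's algorithm with k-means++ seeding. Uses R's RNG (caller set.seed()s).
// Ties in assignment break to the lowest center index; empty clusters are
// re-seeded from the point currently farthest from its assigned center.
// [[Rcpp::export(name = ".lloyd_kmeans_cpp")]]
List lloyd_kmeans_cpp(const NumericMatrix& X, int K, int max_iter, double tol) {
  const int n = X.nrow(), d = X.ncol();
  // row-major copies keep the inner distance loops contiguous
  std::vector<double> xr((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) xr[(size_t)i * d + j] = X(i, j);
  std::vector<double> C((size_t)K * d), dmin(n);
  RNGScope scope;

  // k-means++ seeding
  int first = (int)std::floor(unif_rand() * n);
  if (first >= n) first = n - 1;
  std::copy(&xr[(size_t)first * d], &xr[(size_t)first * d] + d, C.begin());
  for (int i = 0; i < n; ++i)
    dmin[i] = sqdist(&xr[(size_t)i * d], &C[0], d);
  for (int k = 1; k < K; ++k) {
    double total = 0.0;
    for (int i = 0; i < n; ++i) total += dmin[i];
    int pick;
    if (total <= 0.0) {
      pick = (int)std::floor(unif_rand() * n);
      if (pick >= n) pick = n - 1;
    } else {
      const double u = unif_rand() * total;
      double acc = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        acc += dmin[i];
        if (acc >= u) { pick = i; break; }
      }
    }
    double* ck = &C[(size_t)k * d];
    std::copy(&xr[(size_t)pick * d], &xr[(size_t)pick * d] + d, ck);
    for (int i = 0; i < n; ++i) {
      const double dk = sqdist(&xr[(size_t)i * d], ck, d);
      if (dk < dmin[i]) dmin[i] = dk;
    }
  }

  std::vector<int> assign(n, -1), counts(K);
  std::vector<double> sums((size_t)K * d), Cnew((size_t)K * d), inertia_hist;
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // assignment step (ties -> lowest index via strict <)
    double inertia = 0.0;
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      const double* xi = &xr[(size_t)i * d];
      int best = 0;
      double bestd = sqdist(xi, &C[0], d);
      for (int k = 1; k < K; ++k) {
        const double dk = sqdist(xi, &C[(size_t)k * d], d);
        if (dk < bestd) { bestd = dk; best = k; }
      }
      if (assign[i] != best) ++changed;
      assign[i] = best;
      inertia += bestd;
    }
    inertia_hist.push_back(inertia);

    // update step: centers become the member means
    std::fill(counts.begin(), counts.end(), 0);
    std::fill(sums.begin(), sums.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const int a = assign[i];
      ++counts[a];
      const double* xi = &xr[(size_t)i * d];
      double* sa = &sums[(size_t)a * d];
      for (int j = 0; j < d; ++j) sa[j] += xi[j];
    }
    double shift = 0.0;
    std::copy(C.begin(), C.end(), Cnew.begin());
    for (int k = 0; k < K; ++k) {
      if (counts[k] == 0) continue;
      double s = 0.0;
      double* ck = &Cnew[(size_t)k * d];
      const double* sk = &sums[(size_t)k * d];
      for (int j = 0; j < d; ++j) {
        const double nc = sk[j] / counts[k];
        const double diff = nc - C[(size_t)k * d + j];
        s += diff * diff;
        ck[j] = nc;
      }
      if (s > shift) shift = s;
    }
    // re-seed empty clusters from the farthest point (w.r.t. updated centers)
    bool reseeded = false;
    std::vector<bool> taken(n, false);
    for (int k = 0; k < K; ++k) {
      if (counts[k] > 0) continue;
      int far_i = -1;
      double far_d = -1.0;
      for (int i = 0; i < n; ++i) {
        if (taken[i]) continue;
        const double di = sqdist(&xr[(size_t)i * d],
                                 &Cnew[(size_t)assign[i] * d], d);
        if (di > far_d) { far_d = di; far_i = i; }
      }
      if (far_i >= 0) {
        taken[far_i] = true;
        std::copy(&xr[(size_t)far_i * d], &xr[(size_t)far_i * d] + d,
                  &Cnew[(size_t)k * d]);
        reseeded = true;
      }
    }
    C.swap(Cnew);
    if (!reseeded && (std::sqrt(shift) < tol || changed == 0)) {
      ++iter;
      break;
    }
  }

  // final assignment + inertia against the returned centers
  double inertia = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* xi = &xr[(size_t)i * d];
    int best = 0;
    double bestd = sqdist(xi, &C[0], d);
    for (int k = 1; k < K; ++k) {
      const double dk = sqdist(xi, &C[(size_t)k * d], d);
      if (dk < bestd) { bestd = dk; best = k; }
    }
    assign[i] = best;
    inertia += bestd;
  }
  inertia_hist.push_back(inertia);

  NumericMatrix centers(K, d);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < d; ++j) centers(k, j) = C[(size_t)k * d + j];
  IntegerVector asg(n);
  for (int i = 0; i < n; ++i) asg[i] = assign[i] + 1;
  return List::create(_["centers"] = centers, _["assignment"] = asg,
                      _["inertia"] = inertia,
                      _["inertia_history"] = NumericVector(inertia_hist.begin(),
                                                           inertia_hist.end()),
                      _["iterations"] = iter);
}

// Euclidean-nearest center per row of X; ties break to the lowest index.
// [[Rcpp::export(name = ".assign_nearest_cpp")]]
IntegerVector assign_nearest_cpp(const NumericMatrix& X, const NumericMatrix& centers) {
  const int n = X.nrow(), d = X.ncol(), K = centers.nrow();
  std::vector<double> xr((size_t)n * d), cr((size_t)K * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) xr[(size_t)i * d + j] = X(i, j);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < d; ++j) cr[(size_t)k * d + j] = centers(k, j);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &xr[(size_t)i * d];
    int best = 0;
    double bestd = sqdist(xi, &cr[0], d);
    for (int k = 1; k < K; ++k) {
      const double dk = sqdist(xi, &cr[(size_t)k * d], d);
      if (dk < bestd) { bestd = dk; best = k; }
    }
    out[i] = best + 1;
  }
  return out;
}
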