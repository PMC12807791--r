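#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Volumes are passed as flat numeric vectors in R's column-major layout:
// index = i + n1*(j + n2*k) for (row i, col j, frame k).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable running sum over a (2r+1)^3 box with edge clamping, in float.
// Used for the NLM patch distance; r is the patch radius (1 for 3-wide patches).
static void box_sum3(std::vector<float>& a, std::vector<float>& tmp,
                     int n1, int n2, int n3, int r) {
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      const size_t base = (size_t)n1 * (j + (size_t)n2 * k);
      for (int i = 0; i < n1; ++i) {
        float s = 0;
        for (int t = -r; t <= r; ++t) s += a[base + clampi(i + t, 0, n1 - 1)];
        tmp[base + i] = s;
      }
    }
  a.swap(tmp);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      const size_t base = (size_t)n1 * (size_t)n2 * k + i;
      for (int j = 0; j < n2; ++j) {
        float s = 0;
        for (int t = -r; t <= r; ++t) s += a[base + (size_t)n1 * clampi(j + t, 0, n2 - 1)];
        tmp[base + (size_t)n1 * j] = s;
      }
    }
  a.swap(tmp);
  const size_t plane = (size_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      const size_t base = i + (size_t)n1 * j;
      for (int k = 0; k < n3; ++k) {
        float s = 0;
        for (int t = -r; t <= r; ++t) s += a[base + plane * clampi(k + t, 0, n3 - 1)];
        tmp[base + plane * k] = s;
      }
    }
  a.swap(tmp);
}

// 3D non-local means, offset-decomposed: for each search offset the patch
// distance field is a box filter of the squared shifted difference, so the
// cost is O(voxels * offsets) instead of O(voxels * offsets * patch).
// The patch distance between p and p+t is symmetric, so each offset pair
// (t, -t) is visited once and its weight accumulated in both directions;
// near the border, offsets that leave the volume are simply dropped
// (the search window is clipped).
// [[Rcpp::export]]
NumericVector nlm3d_cpp(NumericVector vol, IntegerVector dim,
                        int search_radius, int patch_radius, double h) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const size_t n = (size_t)n1 * n2 * n3;
  const int npatch = (2 * patch_radius + 1) * (2 * patch_radius + 1) *
                     (2 * patch_radius + 1);
  const float inv = (float)(1.0 / (h * h * npatch));
  std::vector<double> num(n, 0.0), den(n, 0.0);
  std::vector<float> d2(n), tmp(n);
  const double* x = REAL(vol);

  // weight lookup: w = exp(-u) tabulated on u in [0, 16) at step 1/64;
  // beyond 16 the weight (< 1.2e-7) is treated as zero
  const int LUTN = 1024;
  const float lut_scale = LUTN / 16.0f;
  std::vector<double> wlut(LUTN);
  for (int i = 0; i < LUTN; ++i)
    wlut[i] = std::exp(-((i + 0.5) / (double)lut_scale));

  // centre offset: weight 1
  for (size_t p = 0; p < n; ++p) { num[p] = x[p]; den[p] = 1.0; }

  const int R = search_radius;
  for (int dk = 0; dk <= R; ++dk)
    for (int dj = (dk == 0 ? 0 : -R); dj <= R; ++dj)
      for (int di = (dk == 0 && dj == 0 ? 1 : -R); di <= R; ++di) {
        // squared difference against the clamped shifted volume
        // (clamping only matters for the patch sums near the border)
        const int i_lo = std::max(0, -di), i_hi = std::min(n1, n1 - di);
        for (int k = 0; k < n3; ++k) {
          const int ks = clampi(k + dk, 0, n3 - 1);
          for (int j = 0; j < n2; ++j) {
            const int js = clampi(j + dj, 0, n2 - 1);
            const double* xr = x + (size_t)n1 * (j + (size_t)n2 * k);
            const double* xs = x + (size_t)n1 * (js + (size_t)n2 * ks);
            float* dr = d2.data() + (size_t)n1 * (j + (size_t)n2 * k);
            for (int i = 0; i < i_lo; ++i) {
              const double d = xr[i] - xs[clampi(i + di, 0, n1 - 1)];
              dr[i] = (float)(d * d);
            }
            const double* xsd = xs + di;
            for (int i = i_lo; i < i_hi; ++i) {
              const double d = xr[i] - xsd[i];
              dr[i] = (float)(d * d);
            }
            for (int i = i_hi; i < n1; ++i) {
              const double d = xr[i] - xs[clampi(i + di, 0, n1 - 1)];
              dr[i] = (float)(d * d);
            }
          }
        }
        box_sum3(d2, tmp, n1, n2, n3, patch_radius);
        // accumulate both directions where p and p+t are in range
        const int k_lo = std::max(0, -dk), k_hi = std::min(n3, n3 - dk);
        const int j_lo = std::max(0, -dj), j_hi = std::min(n2, n2 - dj);
        const long long shift = di + (long long)n1 * dj +
                                (long long)n1 * n2 * dk;
        for (int k = k_lo; k < k_hi; ++k)
          for (int j = j_lo; j < j_hi; ++j) {
            const size_t base = (size_t)n1 * (j + (size_t)n2 * k);
            for (int i = i_lo; i < i_hi; ++i) {
              const size_t p = base + i;
              const float u = d2[p] * inv * lut_scale;
              if (u >= (float)LUTN) continue;
              const size_t q = p + shift;
              const double w = wlut[(int)u];
              num[p] += w * x[q];
              den[p] += w;
              num[q] += w * x[p];
              den[q] += w;
            }
          }
      }

  NumericVector out(n);
  for (size_t p = 0; p < n; ++p) out[p] = num[p] / den[p];
  out.attr("dim") = dim;
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), one scanline.
static void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform of a binary mask (distance of each
// foreground voxel to the nearest background voxel, isotropic voxel units).
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const size_t n = (size_t)n1 * n2 * n3;
  const double INF = 1e20;
  std::vector<double> d(n);
  for (size_t p = 0; p < n; ++p) d[p] = mask[p] ? INF : 0.0;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      const size_t base = (size_t)n1 * (j + (size_t)n2 * k);
      for (int i = 0; i < n1; ++i) f[i] = d[base + i];
      dt1d(f.data(), dd.data(), n1, v.data(), z.data());
      for (int i = 0; i < n1; ++i) d[base + i] = dd[i];
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      const size_t base = (size_t)n1 * (size_t)n2 * k + i;
      for (int j = 0; j < n2; ++j) f[j] = d[base + (size_t)n1 * j];
      dt1d(f.data(), dd.data(), n2, v.data(), z.data());
      for (int j = 0; j < n2; ++j) d[base + (size_t)n1 * j] = dd[j];
    }
  // axis 3
  const size_t plane = (size_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      const size_t base = i + (size_t)n1 * j;
      for (int k = 0; k < n3; ++k) f[k] = d[base + plane * k];
      dt1d(f.data(), dd.data(), n3, v.data(), z.data());
      for (int k = 0; k < n3; ++k) d[base + plane * k] = dd[k];
    }

  NumericVector out(n);
  for (size_t p = 0; p < n; ++p) out[p] = std::sqrt(d[p]);
  out.attr("dim") = dim;
  return out;
}

// Separable running maximum over a (2r+1)^3 box (edge-clamped).
// [[Rcpp::export]]
NumericVector maxfilter3d_cpp(NumericVector vol, IntegerVector dim, int r) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const size_t n = (size_t)n1 * n2 * n3;
  std::vector<double> a(REAL(vol), REAL(vol) + n), tmp(n);

  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      const size_t base = (size_t)n1 * (j + (size_t)n2 * k);
      for (int i = 0; i < n1; ++i) {
        double m = -1e300;
        for (int t = std::max(0, i - r); t <= std::min(n1 - 1, i + r); ++t)
          m = std::max(m, a[base + t]);
        tmp[base + i] = m;
      }
    }
  a.swap(tmp);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      const size_t base = (size_t)n1 * (size_t)n2 * k + i;
      for (int j = 0; j < n2; ++j) {
        double m = -1e300;
        for (int t = std::max(0, j - r); t <= std::min(n2 - 1, j + r); ++t)
          m = std::max(m, a[base + (size_t)n1 * t]);
        tmp[base + (size_t)n1 * j] = m;
      }
    }
  a.swap(tmp);
  const size_t plane = (size_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      const size_t base = i + (size_t)n1 * j;
      for (int k = 0; k < n3; ++k) {
        double m = -1e300;
        for (int t = std::max(0, k - r); t <= std::min(n3 - 1, k + r); ++t)
          m = std::max(m, a[base + plane * t]);
        tmp[base + plane * k] = m;
      }
    }
  a.swap(tmp);

  NumericVector out(n);
  for (size_t p = 0; p < n; ++p) out[p] = a[p];
  out.attr("dim") = dim;
  return out;
}

// 6-connected component labelling of a binary mask (BFS).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const size_t n = (size_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<size_t> stack;
  int next = 0;
  const long long off[6] = {-1, 1, -(long long)n1, (long long)n1,
                            -(long long)n1 * n2, (long long)n1 * n2};
  for (size_t p = 0; p < n; ++p) {
    if (!mask[p] || lab[p] != 0) continue;
    ++next;
    lab[p] = next;
    stack.push_back(p);
    while (!stack.empty()) {
      const size_t q = stack.back();
      stack.pop_back();
      const int i = q % n1, j = (q / n1) % n2, k = q / ((size_t)n1 * n2);
      for (int t = 0; t < 6; ++t) {
        if (t == 0 && i == 0) continue;
        if (t == 1 && i == n1 - 1) continue;
        if (t == 2 && j == 0) continue;
        if (t == 3 && j == n2 - 1) continue;
        if (t == 4 && k == 0) continue;
        if (t == 5 && k == n3 - 1) continue;
        const size_t r = q + off[t];
        if (mask[r] && lab[r] == 0) { lab[r] = next; stack.push_back(r); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

struct QItem {
  double prio;
  unsigned long order;
  size_t idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;  // max-heap on priority
    return a.order > b.order;                      // FIFO on ties
  }
};

// Seeded watershed by priority flooding: voxels are flooded in order of
// decreasing distance-map value, each taking the label of the neighbour
// that reached it first (6-connectivity, restricted to the mask).
// [[Rcpp::export]]
IntegerVector watershed3d_cpp(NumericVector dist, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const size_t n = (size_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  unsigned long order = 0;
  const long long off[6] = {-1, 1, -(long long)n1, (long long)n1,
                            -(long long)n1 * n2, (long long)n1 * n2};

  for (size_t p = 0; p < n; ++p)
    if (seeds[p] > 0 && mask[p]) {
      lab[p] = seeds[p];
      pq.push({dist[p], order++, p});
    }

  while (!pq.empty()) {
    const size_t q = pq.top().idx;
    pq.pop();
    const int i = q % n1, j = (q / n1) % n2, k = q / ((size_t)n1 * n2);
    for (int t = 0; t < 6; ++t) {
      if (t == 0 && i == 0) continue;
      if (t == 1 && i == n1 - 1) continue;
      if (t == 2 && j == 0) continue;
      if (t == 3 && j == n2 - 1) continue;
      if (t == 4 && k == 0) continue;
      if (t == 5 && k == n3 - 1) continue;
      const size_t r = q + off[t];
      if (mask[r] && lab[r] == 0) {
        lab[r] = lab[q];
        pq.push({dist[r], order++, r});
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
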