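#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Index helpers for a column-major 3D array with dims (d1, d2, d3).
static inline int reflect_index(int i, int n) {
  // scipy-style "reflect" boundary: (d c b a | a b c d | d c b a)
  if (n == 1) return 0;
  const int period = 2 * n;
  i = ((i % period) + period) % period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// 1D convolution along one axis of a 3D array, reflective boundaries.
// kernel has odd length; axis is 1, 2 or 3 (fastest to slowest varying).
// [[Rcpp::export]]
NumericVector conv3d_axis(NumericVector vol, IntegerVector dims,
                          NumericVector kernel, int axis) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int klen = kernel.size(), half = klen / 2;
  NumericVector out(vol.size());
  const double *x = vol.begin();
  double *y = out.begin();
  const double *k = kernel.begin();

  // one 1D line at a time; interior positions take the stride-only fast path
  auto line = [&](const int base, const int n, const int stride) {
    const int lo = std::min(half, n);
    const int hi = std::max(lo, n - half);
    for (int a = 0; a < lo; ++a) {
      double s = 0.0;
      for (int t = 0; t < klen; ++t)
        s += k[t] * x[base + reflect_index(a + t - half, n) * stride];
      y[base + a * stride] = s;
    }
    for (int a = lo; a < hi; ++a) {
      double s = 0.0;
      const double *xp = x + base + (a - half) * stride;
      for (int t = 0; t < klen; ++t, xp += stride) s += k[t] * (*xp);
      y[base + a * stride] = s;
    }
    for (int a = hi; a < n; ++a) {
      double s = 0.0;
      for (int t = 0; t < klen; ++t)
        s += k[t] * x[base + reflect_index(a + t - half, n) * stride];
      y[base + a * stride] = s;
    }
  };

  if (axis == 1) {
    for (int c = 0; c < d3; ++c)
      for (int b = 0; b < d2; ++b)
        line((c * d2 + b) * d1, d1, 1);
  } else if (axis == 2) {
    for (int c = 0; c < d3; ++c)
      for (int a = 0; a < d1; ++a)
        line(c * d2 * d1 + a, d2, d1);
  } else {
    for (int b = 0; b < d2; ++b)
      for (int a = 0; a < d1; ++a)
        line(b * d1 + a, d3, d1 * d2);
  }
  return out;
}

// Strict 26-connected local maxima of a 3D array. Out-of-volume neighbors
// are treated as -Inf so border maxima are admissible. Returns 0-based
// linear indices of the maxima.
// [[Rcpp::export]]
IntegerVector local_maxima_26(NumericVector vol, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double *x = vol.begin();
  std::vector<int> hits;
  for (int c = 0; c < d3; ++c)
    for (int b = 0; b < d2; ++b)
      for (int a = 0; a < d1; ++a) {
        const double v = x[(c * d2 + b) * d1 + a];
        bool is_max = true;
        for (int dc = -1; dc <= 1 && is_max; ++dc)
          for (int db = -1; db <= 1 && is_max; ++db)
            for (int da = -1; da <= 1; ++da) {
              if (da == 0 && db == 0 && dc == 0) continue;
              const int aa = a + da, bb = b + db, cc = c + dc;
              if (aa < 0 || aa >= d1 || bb < 0 || bb >= d2 ||
                  cc < 0 || cc >= d3) continue;
              if (x[(cc * d2 + bb) * d1 + aa] >= v) { is_max = false; break; }
            }
        if (is_max) hits.push_back((c * d2 + b) * d1 + a);
      }
  return IntegerVector(hits.begin(), hits.end());
}

// 6-connected component labelling of a logical 3D mask (BFS flood fill).
// Returns an integer array of the same shape, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components_6(LogicalVector mask, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int n = mask.size();
  IntegerVector lab(n, 0);
  const int da[6] = {1, -1, 0, 0, 0, 0};
  const int db[6] = {0, 0, 1, -1, 0, 0};
  const int dc[6] = {0, 0, 0, 0, 1, -1};
  int next = 0;
  std::queue<int> q;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    lab[idx] = ++next;
    q.push(idx);
    while (!q.empty()) {
      const int cur = q.front(); q.pop();
      const int a = cur % d1, b = (cur / d1) % d2, c = cur / (d1 * d2);
      for (int t = 0; t < 6; ++t) {
        const int aa = a + da[t], bb = b + db[t], cc = c + dc[t];
        if (aa < 0 || aa >= d1 || bb < 0 || bb >= d2 || cc < 0 || cc >= d3)
          continue;
        const int nb = (cc * d2 + bb) * d1 + aa;
        if (mask[nb] && lab[nb] == 0) { lab[nb] = next; q.push(nb); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Additive rendering of an isotropic 3D Gaussian into a (z, y, x) volume.
// Positions and sigma are in physical units; vox = (dz, dy, dx) matches the
// array axis order. Truncated at 3.5 sigma.
// [[Rcpp::export]]
NumericVector render_gaussian_add(NumericVector vol, IntegerVector dims,
                                  NumericVector center_zyx, double sigma,
                                  double amplitude, NumericVector vox) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double cz = center_zyx[0], cy = center_zyx[1], cx = center_zyx[2];
  const double dz = vox[0], dy = vox[1], dx = vox[2];
  const double reach = 3.5 * sigma;
  const int z0 = std::max(0, (int)std::floor((cz - reach) / dz));
  const int z1 = std::min(d1 - 1, (int)std::ceil((cz + reach) / dz));
  const int y0 = std::max(0, (int)std::floor((cy - reach) / dy));
  const int y1 = std::min(d2 - 1, (int)std::ceil((cy + reach) / dy));
  const int x0 = std::max(0, (int)std::floor((cx - reach) / dx));
  const int x1 = std::min(d3 - 1, (int)std::ceil((cx + reach) / dx));
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double *v = vol.begin();
  for (int xi = x0; xi <= x1; ++xi) {
    const double rx = xi * dx - cx;
    for (int yi = y0; yi <= y1; ++yi) {
      const double ry = yi * dy - cy;
      const double rxy = rx * rx + ry * ry;
      for (int zi = z0; zi <= z1; ++zi) {
        const double rz = zi * dz - cz;
        v[(xi * d2 + yi) * d1 + zi] += amplitude * std::exp(-(rxy + rz * rz) * inv2s2);
      }
    }
  }
  return vol;
}
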