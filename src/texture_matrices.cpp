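#include <Rcpp.h>
#include <vector>
#include <deque>
using namespace Rcpp;

// 13 unique 3D direction vectors at Chebyshev distance 1 (half of the 26
// neighbours; the opposite offsets are covered by symmetrization / run scans).
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int vidx(int i, int j, int k, int d0, int d1) {
  return i + d0 * (j + d1 * k);
}

// Gray-level co-occurrence counts, one Ng x Ng slab per direction.
// `levels` holds 1..ng inside the mask and 0 outside.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dim, int ng) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  NumericVector out(ng * ng * 13);
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        int li = levels[vidx(i, j, k, d0, d1)];
        if (li == 0) continue;
        for (int d = 0; d < 13; ++d) {
          int ni = i + DIRS[d][0], nj = j + DIRS[d][1], nk = k + DIRS[d][2];
          if (ni < 0 || nj < 0 || nk < 0 || ni >= d0 || nj >= d1 || nk >= d2)
            continue;
          int lj = levels[vidx(ni, nj, nk, d0, d1)];
          if (lj == 0) continue;
          // symmetric accumulation
          out[(li - 1) + ng * (lj - 1) + ng * ng * d] += 1.0;
          out[(lj - 1) + ng * (li - 1) + ng * ng * d] += 1.0;
        }
      }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Run-length counts, Ng x maxlen slab per direction. A run starts at a voxel
// whose predecessor along the direction is absent (out of grid / out of mask /
// different level) and extends forward while the level repeats.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector levels, IntegerVector dim, int ng) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  int maxlen = std::max(d0, std::max(d1, d2));
  NumericVector out(ng * maxlen * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int k = 0; k < d2; ++k)
      for (int j = 0; j < d1; ++j)
        for (int i = 0; i < d0; ++i) {
          int li = levels[vidx(i, j, k, d0, d1)];
          if (li == 0) continue;
          int pi = i - dx, pj = j - dy, pk = k - dz;
          if (pi >= 0 && pj >= 0 && pk >= 0 && pi < d0 && pj < d1 && pk < d2 &&
              levels[vidx(pi, pj, pk, d0, d1)] == li)
            continue;  // interior of a run
          int len = 1;
          int ci = i + dx, cj = j + dy, ck = k + dz;
          while (ci >= 0 && cj >= 0 && ck >= 0 && ci < d0 && cj < d1 && ck < d2 &&
                 levels[vidx(ci, cj, ck, d0, d1)] == li) {
            ++len; ci += dx; cj += dy; ck += dz;
          }
          out[(li - 1) + ng * (len - 1) + ng * maxlen * d] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// Size-zone decomposition: 26-connected components of constant level within
// the mask. Returns one row per zone: (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, IntegerVector dim) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  int n = d0 * d1 * d2;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::deque<int> q;
  for (int s = 0; s < n; ++s) {
    if (seen[s] || levels[s] == 0) continue;
    int lev = levels[s], size = 0;
    seen[s] = 1; q.push_back(s);
    while (!q.empty()) {
      int v = q.front(); q.pop_front();
      ++size;
      int k = v / (d0 * d1), r = v % (d0 * d1), j = r / d0, i = r % d0;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ni = i + di, nj = j + dj, nk = k + dk;
            if (ni < 0 || nj < 0 || nk < 0 || ni >= d0 || nj >= d1 || nk >= d2)
              continue;
            int w = vidx(ni, nj, nk, d0, d1);
            if (!seen[w] && levels[w] == lev) { seen[w] = 1; q.push_back(w); }
          }
    }
    zl.push_back(lev); zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t z = 0; z < zl.size(); ++z) { out(z, 0) = zl[z]; out(z, 1) = zs[z]; }
  return out;
}

// Dependence counts: for each masked voxel, the number of its 26 masked
// neighbours whose level differs by at most alpha. Returns Ng x 27 counts
// (columns index dependence 0..26).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dim, int ng, int alpha) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  NumericMatrix out(ng, 27);
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        int li = levels[vidx(i, j, k, d0, d1)];
        if (li == 0) continue;
        int dep = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ni = i + di, nj = j + dj, nk = k + dk;
              if (ni < 0 || nj < 0 || nk < 0 || ni >= d0 || nj >= d1 || nk >= d2)
                continue;
              int lj = levels[vidx(ni, nj, nk, d0, d1)];
              if (lj != 0 && std::abs(lj - li) <= alpha) ++dep;
            }
        out(li - 1, dep) += 1.0;
      }
  return out;
}

// NGTDM accumulators: per level i, the voxel count n_i and the summed absolute
// difference s_i between the level and the mean of its valid 26-neighbourhood.
// Voxels with no valid neighbour contribute to n_i with zero difference.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ng) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  NumericMatrix out(ng, 2);
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        int li = levels[vidx(i, j, k, d0, d1)];
        if (li == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ni = i + di, nj = j + dj, nk = k + dk;
              if (ni < 0 || nj < 0 || nk < 0 || ni >= d0 || nj >= d1 || nk >= d2)
                continue;
              int lj = levels[vidx(ni, nj, nk, d0, d1)];
              if (lj != 0) { sum += lj; ++cnt; }
            }
        out(li - 1, 0) += 1.0;
        if (cnt > 0) out(li - 1, 1) += std::abs(li - sum / cnt);
      }
  return out;
}

// Separable 1D convolution along one axis of a 3D array.
// mode 0: replicate edge padding; mode 1: periodic (circular) padding.
// `origin` is the kernel tap aligned with the output voxel (0-based).
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis, int mode,
                            int origin) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  int L = kernel.size();
  int ext[3] = {d0, d1, d2};
  int n = ext[axis];
  NumericVector out(vol.size());
  int stride = (axis == 0) ? 1 : (axis == 1 ? d0 : d0 * d1);
  // iterate over all lines along `axis`
  int nlines = (d0 * d1 * d2) / n;
  std::vector<double> line(n);
  int a1, a2, s1, s2, e1, e2;
  if (axis == 0) { s1 = d0; s2 = d0 * d1; e1 = d1; e2 = d2; }
  else if (axis == 1) { s1 = 1; s2 = d0 * d1; e1 = d0; e2 = d2; }
  else { s1 = 1; s2 = d0; e1 = d0; e2 = d1; }
  (void)nlines;
  for (a2 = 0; a2 < e2; ++a2)
    for (a1 = 0; a1 < e1; ++a1) {
      int base = a1 * s1 + a2 * s2;
      for (int t = 0; t < n; ++t) line[t] = vol[base + t * stride];
      for (int t = 0; t < n; ++t) {
        double acc = 0.0;
        for (int m = 0; m < L; ++m) {
          int src = t + (m - origin);
          if (mode == 1) {
            src %= n; if (src < 0) src += n;
          } else {
            if (src < 0) src = 0; else if (src >= n) src = n - 1;
          }
          acc += kernel[m] * line[src];
        }
        out[base + t * stride] = acc;
      }
    }
  out.attr("dim") = dim;
  return out;
}
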