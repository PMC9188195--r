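#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// All voxel grids are passed as flat logical/integer vectors in R's
// column-major order together with a length-3 dims vector; 2D images use
// dims[2] == 1 so one code path serves both section images and volumes.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Connected-component labelling by breadth-first search.
// full = false: face adjacency (4-connectivity in 2D, 6 in 3D);
// full = true : all neighbouring voxels sharing a vertex (8 in 2D, 26 in 3D).
// Labels are assigned in order of the first voxel (column-major) of each
// component, so output is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   bool full) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);

  std::vector<std::array<int,3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int nz_off = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (!full && nz_off != 1) continue;
        nb.push_back({di, dj, dk});
      }

  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int i = v % nx, rem = v / nx;
      int j = rem % ny, k = rem / ny;
      for (const auto &d : nb) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        int w = idx3(ii, jj, kk, nx, ny);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// Background voxels start at this sentinel rather than Inf so the
// lower-envelope recursion below stays finite; anything at or above
// BIG/1e6 on output means "no foreground voxel reachable".
static const double BIG = 1e30;

// One-dimensional squared distance transform (lower envelope of parabolas),
// with physical sample spacing h. f holds squared distances on input.
static void dt1d(std::vector<double> &f, int n, double h,
                 std::vector<double> &d, std::vector<int> &v,
                 std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * (double)v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (k > 0 && s <= z[k]) { --k; } else break;
    }
    if (s <= z[k]) { // k == 0 and new parabola dominates everywhere
      v[0] = q;
      z[0] = -std::numeric_limits<double>::infinity();
      z[1] = std::numeric_limits<double>::infinity();
      k = 0;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = std::numeric_limits<double>::infinity();
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance from every voxel to the nearest TRUE voxel,
// with anisotropic physical spacing (micrometres per voxel along each axis).
// Voxels are treated as points at their centres; if no voxel is TRUE the
// result is Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (fg.size() != n) stop("input length does not match dims");
  NumericVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = fg[s] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = out[idx3(i, j, k, nx, ny)];
      dt1d(f, nx, spacing[0], d, v, z);
      for (int i = 0; i < nx; ++i) out[idx3(i, j, k, nx, ny)] = f[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = out[idx3(i, j, k, nx, ny)];
      dt1d(f, ny, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) out[idx3(i, j, k, nx, ny)] = f[j];
    }
  // along z
  if (nz > 1)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) f[k] = out[idx3(i, j, k, nx, ny)];
        dt1d(f, nz, spacing[2], d, v, z);
        for (int k = 0; k < nz; ++k) out[idx3(i, j, k, nx, ny)] = f[k];
      }
  for (R_xlen_t s = 0; s < n; ++s)
    if (out[s] >= BIG / 1e6) out[s] = R_PosInf;
  return out;
}

// Geodesic nearest-peak assignment within a binary mask: every mask voxel
// receives the label (1-based row of `peaks`) of the peak with the smallest
// in-mask geodesic distance, paths restricted to face-adjacent mask voxels
// with per-axis step costs `spacing`. Ties go to the smaller peak label.
// Exact per-peak Dijkstra, so the result equals brute-force nearest-peak
// search by construction. Mask voxels unreachable from every peak keep 0.
// [[Rcpp::export]]
IntegerVector cpp_geodesic_labels(LogicalVector mask, IntegerVector dims,
                                  IntegerMatrix peaks, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> best(n, INF), dist(n);
  IntegerVector lab(n, 0);

  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  const double hc[6] = {spacing[0], spacing[0], spacing[1], spacing[1],
                        spacing[2], spacing[2]};

  typedef std::pair<double, int> QE; // (distance, voxel)
  for (int p = 0; p < peaks.nrow(); ++p) {
    int i0 = peaks(p, 0) - 1, j0 = peaks(p, 1) - 1, k0 = peaks(p, 2) - 1;
    if (i0 < 0 || i0 >= nx || j0 < 0 || j0 >= ny || k0 < 0 || k0 >= nz)
      stop("peak outside volume");
    std::fill(dist.begin(), dist.end(), INF);
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
    int s0 = idx3(i0, j0, k0, nx, ny);
    dist[s0] = 0.0;
    pq.push({0.0, s0});
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      double dcur = top.first;
      int v = top.second;
      if (dcur > dist[v]) continue;
      int i = v % nx, rem = v / nx;
      int j = rem % ny, k = rem / ny;
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        int w = idx3(ii, jj, kk, nx, ny);
        if (!mask[w]) continue;
        double nd = dcur + hc[m];
        if (nd < dist[w]) {
          dist[w] = nd;
          pq.push({nd, w});
        }
      }
    }
    for (R_xlen_t s = 0; s < n; ++s) {
      if (!mask[s]) continue;
      if (dist[s] < best[s]) { // strict: ties keep the smaller label
        best[s] = dist[s];
        lab[s] = p + 1;
      }
    }
  }
  return lab;
}
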