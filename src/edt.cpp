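#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope algorithm), separable over the three axes. Distances are in
// squared voxel units, so they are exact integers representable in doubles.

namespace {

// "No feature in range": any value >= BIG is treated as unreachable. BIG is
// finite so the parabola algebra stays well defined; sentinel parabolas can
// never undercut a genuine one inside the propagation band, so distances
// below BIG remain exact integers.
const double INF = 1e15;
const double SENTINEL_CUT = 1e14;

// 1D squared distance transform under the lower envelope of parabolas
// (Felzenszwalb & Huttenlocher).
void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF * 10;
  z[1] = INF * 10;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF * 10;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

} // namespace

// Squared EDT to the nearest feature voxel (feature <=> surf_id > 0).
// Returns squared distances in voxel units (0 at features, large where no
// feature is reachable).
// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector surf_id, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;
  NumericVector D(n);

  // pass 1: along x, exact 1D distance by two sweeps
  for (R_xlen_t jk = 0; jk < (R_xlen_t)ny * nz; ++jk) {
    const R_xlen_t base = jk * nx;
    double last = INF;
    for (int i = 0; i < nx; ++i) {
      if (surf_id[base + i] > 0) last = 0.0; else if (last < INF) last += 1.0;
      D[base + i] = last;
    }
    last = INF;
    for (int i = nx - 1; i >= 0; --i) {
      if (surf_id[base + i] > 0) last = 0.0; else if (last < INF) last += 1.0;
      if (last < D[base + i]) D[base + i] = last;
    }
    for (int i = 0; i < nx; ++i) {
      double d = D[base + i];
      D[base + i] = (d >= INF) ? INF : d * d;
    }
  }

  const int nmax = std::max(ny, nz);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass 2: along y
  for (int k = 0; k < nz; ++k) {
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)k * nxy + i;
      for (int j = 0; j < ny; ++j) f[j] = D[base + (R_xlen_t)j * nx];
      bool any = false;
      for (int j = 0; j < ny; ++j) if (f[j] < INF) { any = true; break; }
      if (!any) continue;
      dt1d(f.data(), d.data(), ny, v.data(), z.data());
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)j * nx] = d[j];
    }
  }

  // pass 3: along z
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = D[base + (R_xlen_t)k * nxy];
      bool any = false;
      for (int k = 0; k < nz; ++k) if (f[k] < INF) { any = true; break; }
      if (!any) continue;
      dt1d(f.data(), d.data(), nz, v.data(), z.data());
      for (int k = 0; k < nz; ++k) D[base + (R_xlen_t)k * nxy] = d[k];
    }
  }
  return D;
}

// Resolve, for every voxel in the propagation band, the id of its nearest
// surface element. The squared distance D2 (integer, voxel units) is known
// from the EDT; all lattice offsets with |o|^2 == D2 are enumerated in
// ascending (dz, dy, dx) order, which equals ascending linear index of the
// candidate position, hence ascending surface-element id (ids are assigned
// in ascending linear-index order). Ties therefore resolve to the smallest
// element id, independently of any slab decomposition.
// [[Rcpp::export]]
IntegerVector cpp_resolve_sources(NumericVector D2, IntegerVector surf_id,
                                  LogicalVector occupied, IntegerVector dims,
                                  int max_r2) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;
  IntegerVector src(n, 0);

  const int R = (int)std::floor(std::sqrt((double)max_r2));
  // shell table: offsets grouped by squared norm, ordered by (dz, dy, dx)
  struct Off { int r2, dz, dy, dx; };
  std::vector<Off> offs;
  offs.reserve((size_t)(2 * R + 1) * (2 * R + 1) * (2 * R + 1) / 2 + 8);
  for (int dz = -R; dz <= R; ++dz)
    for (int dy = -R; dy <= R; ++dy)
      for (int dx = -R; dx <= R; ++dx) {
        int r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= max_r2) offs.push_back({r2, dz, dy, dx});
      }
  std::sort(offs.begin(), offs.end(), [](const Off& a, const Off& b) {
    if (a.r2 != b.r2) return a.r2 < b.r2;
    if (a.dz != b.dz) return a.dz < b.dz;
    if (a.dy != b.dy) return a.dy < b.dy;
    return a.dx < b.dx;
  });
  std::vector<R_xlen_t> start(max_r2 + 2, (R_xlen_t)offs.size());
  for (R_xlen_t t = (R_xlen_t)offs.size() - 1; t >= 0; --t) start[offs[t].r2] = t;

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t rowbase = (R_xlen_t)k * nxy + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = rowbase + i;
        if (occupied[idx]) continue;
        const double d2d = D2[idx];
        if (d2d <= 0.0 || d2d > (double)max_r2) continue;
        const int d2 = (int)(d2d + 0.5);
        int found = 0;
        for (R_xlen_t t = start[d2]; t < (R_xlen_t)offs.size(); ++t) {
          if (offs[t].r2 != d2) break;
          const int ii = i + offs[t].dx;
          const int jj = j + offs[t].dy;
          const int kk = k + offs[t].dz;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          const int id = surf_id[(R_xlen_t)kk * nxy + (R_xlen_t)jj * nx + ii];
          if (id > 0) { found = id; break; }
        }
        src[idx] = found; // 0 never happens when D2 comes from cpp_edt3d
      }
    }
  }
  return src;
}
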