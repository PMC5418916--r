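#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rasterize a union of finite cylinders (tapered tubes) into a voxel grid.
// segments: n x 8 matrix (x0 y0 z0 x1 y1 z1 r0 r1), all in mm.
// A voxel is occupied iff its center projects onto some segment
// (0 <= t <= 1) at perpendicular distance <= the linearly interpolated
// radius r(t). Flat-ended on purpose: the occupied volume of a straight
// tube of length L is pi R^2 L, without spherical caps.
// Voxel centers sit at ((i + 0.5) * pixel) mm, i = 0 .. dims - 1.
// [[Rcpp::export]]
LogicalVector cpp_rasterize(NumericMatrix segments, IntegerVector dims,
                            double pixel_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n_vox = (R_xlen_t)nx * ny * nz;
  LogicalVector occ(n_vox, false);
  const double v = pixel_mm;

  for (int s = 0; s < segments.nrow(); ++s) {
    const double x0 = segments(s, 0), y0 = segments(s, 1), z0 = segments(s, 2);
    const double x1 = segments(s, 3), y1 = segments(s, 4), z1 = segments(s, 5);
    const double r0 = segments(s, 6), r1 = segments(s, 7);
    const double rmax = std::max(r0, r1);
    const double ax = x1 - x0, ay = y1 - y0, az = z1 - z0;
    const double len2 = ax * ax + ay * ay + az * az;

    const int i0 = std::max(0, (int)std::floor((std::min(x0, x1) - rmax) / v - 0.5));
    const int i1 = std::min(nx - 1, (int)std::ceil((std::max(x0, x1) + rmax) / v - 0.5));
    const int j0 = std::max(0, (int)std::floor((std::min(y0, y1) - rmax) / v - 0.5));
    const int j1 = std::min(ny - 1, (int)std::ceil((std::max(y0, y1) + rmax) / v - 0.5));
    const int k0 = std::max(0, (int)std::floor((std::min(z0, z1) - rmax) / v - 0.5));
    const int k1 = std::min(nz - 1, (int)std::ceil((std::max(z0, z1) + rmax) / v - 0.5));

    for (int k = k0; k <= k1; ++k) {
      const double pz = (k + 0.5) * v;
      for (int j = j0; j <= j1; ++j) {
        const double py = (j + 0.5) * v;
        for (int i = i0; i <= i1; ++i) {
          const double px = (i + 0.5) * v;
          const double wx = px - x0, wy = py - y0, wz = pz - z0;
          double t;
          if (len2 <= 0.0) {
            t = 0.0;
          } else {
            t = (wx * ax + wy * ay + wz * az) / len2;
          }
          if (t < 0.0 || t > 1.0) continue;
          const double dxp = wx - t * ax, dyp = wy - t * ay, dzp = wz - t * az;
          const double r = r0 + t * (r1 - r0);
          if (dxp * dxp + dyp * dyp + dzp * dzp <= r * r) {
            occ[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = true;
          }
        }
      }
    }
  }
  return occ;
}

// Nearest point lookup: for each query row (x,y,z) return the 1-based index
// of the closest reference point. Brute force; both sets are modest.
// [[Rcpp::export]]
IntegerVector cpp_nearest_point(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("no reference points");
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    double best = R_PosInf;
    int best_i = 0;
    for (int r = 0; r < nr; ++r) {
      const double dx = ref(r, 0) - qx;
      const double dy = ref(r, 1) - qy;
      const double dz = ref(r, 2) - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; best_i = r; }
    }
    out[q] = best_i + 1;
  }
  return out;
}
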