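// Ray-parity voxelization of a closed triangle mesh.
//
// Casts one ray per (x, y) sample column along +z, collects crossing
// depths with every triangle, and integrates the inside intervals exactly
// against the voxel z-bins (no z sampling error). Sample columns are
// expected to be placed in generic position (jittered off any mesh plane)
// by the R caller; triangles degenerate in the xy projection are skipped,
// which is exact for rays that do not graze them.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// xc, yc: fine column sample coordinates (sx * nx and sy * ny of them,
// regularly spaced); zb: nz + 1 ascending voxel boundaries.
// Returns an nx * ny * nz array of per-voxel inside fractions, where each
// coarse voxel aggregates sx * sy columns.
// [[Rcpp::export]]
NumericVector ray_parity_occupancy(NumericMatrix V, IntegerMatrix F,
                                   NumericVector xc, NumericVector yc,
                                   NumericVector zb,
                                   int sx, int sy) {
  const int nfx = xc.size(), nfy = yc.size();
  const int nx = nfx / sx, ny = nfy / sy;
  const int nz = zb.size() - 1;
  const int ncol = nfx * nfy;
  std::vector<std::vector<double>> hits(ncol);

  const int nf = F.nrow();
  // column coordinates may be unevenly spaced (low-discrepancy jitter);
  // locate bbox-covered index ranges by binary search on the sorted values
  std::vector<double> xv(xc.begin(), xc.end());
  std::vector<double> yv(yc.begin(), yc.end());

  for (int t = 0; t < nf; ++t) {
    const int i1 = F(t, 0) - 1, i2 = F(t, 1) - 1, i3 = F(t, 2) - 1;
    const double ax = V(i1, 0), ay = V(i1, 1), az = V(i1, 2);
    const double bx = V(i2, 0), by = V(i2, 1), bz = V(i2, 2);
    const double cx = V(i3, 0), cy = V(i3, 1), cz = V(i3, 2);
    const double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (det == 0.0) continue;  // vertical / degenerate in xy projection
    const double xmin = std::min(ax, std::min(bx, cx));
    const double xmax = std::max(ax, std::max(bx, cx));
    const double ymin = std::min(ay, std::min(by, cy));
    const double ymax = std::max(ay, std::max(by, cy));
    const int ix_lo = (int)(std::lower_bound(xv.begin(), xv.end(), xmin) -
                            xv.begin());
    const int ix_hi = (int)(std::upper_bound(xv.begin(), xv.end(), xmax) -
                            xv.begin()) - 1;
    const int iy_lo = (int)(std::lower_bound(yv.begin(), yv.end(), ymin) -
                            yv.begin());
    const int iy_hi = (int)(std::upper_bound(yv.begin(), yv.end(), ymax) -
                            yv.begin()) - 1;
    for (int iy = iy_lo; iy <= iy_hi; ++iy) {
      const double py = yv[iy];
      for (int ix = ix_lo; ix <= ix_hi; ++ix) {
        const double px = xv[ix];
        // barycentric coordinates in the xy projection
        const double l1 = ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / det;
        const double l2 = ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / det;
        const double l3 = 1.0 - l1 - l2;
        if (l1 <= 0.0 || l2 <= 0.0 || l3 <= 0.0) continue;  // strict interior
        const double z = l1 * az + l2 * bz + l3 * cz;
        hits[iy * nfx + ix].push_back(z);
      }
    }
  }

  NumericVector out(R_xlen_t(nx) * ny * nz);
  const double inv_cols = 1.0 / (double(sx) * sy);
  for (int iy = 0; iy < nfy; ++iy) {
    const int cy_ = iy / sy;
    for (int ix = 0; ix < nfx; ++ix) {
      std::vector<double> &h = hits[iy * nfx + ix];
      if (h.empty()) continue;
      std::sort(h.begin(), h.end());
      // odd crossing counts mean the ray grazed something; drop the
      // column rather than poison the integral (jitter makes this rare)
      if (h.size() % 2 != 0) continue;
      const int cx_ = ix / sx;
      const R_xlen_t base = cx_ + R_xlen_t(nx) * cy_;
      // accumulate overlap of each inside interval with the z bins
      size_t p = 0;
      int iz = 0;
      while (p + 1 < h.size()) {
        const double lo = h[p], hi = h[p + 1];
        p += 2;
        while (iz < nz && zb[iz + 1] <= lo) ++iz;
        int jz = iz;
        while (jz < nz && zb[jz] < hi) {
          const double a = std::max(lo, (double)zb[jz]);
          const double b = std::min(hi, (double)zb[jz + 1]);
          if (b > a)
            out[base + R_xlen_t(nx) * ny * jz] +=
              (b - a) / (zb[jz + 1] - zb[jz]) * inv_cols;
          ++jz;
        }
      }
    }
  }
  return out;
}
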