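#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cast full lines (both senses) through seed points for each direction and
// count bone/void phase crossings between consecutive visited voxels, using
// an incremental voxel-traversal (Amanatides-Woo) walk in world (mm)
// parameterisation. Voxel i (0-based) spans [(i-0.5)*sp, (i+0.5)*sp) mm on
// each axis; the ROI box is given as 0-based inclusive index bounds.
//
// vol:     logical voxel array, x fastest
// dims:    nx, ny, nz
// spacing: mm per axis
// points:  n x 3 seed coordinates in mm (must lie inside the ROI box)
// dirs:    m x 3 unit direction vectors (world frame)
// roi_lo, roi_hi: 0-based inclusive voxel index bounds of the ROI
//
// Returns per-direction total line length (mm) and crossing counts.
// [[Rcpp::export]]
List mil_crossings_cpp(LogicalVector vol, IntegerVector dims,
                       NumericVector spacing, NumericMatrix points,
                       NumericMatrix dirs, IntegerVector roi_lo,
                       IntegerVector roi_hi) {
  const int nx = dims[0], ny = dims[1];
  const int npts = points.nrow(), ndir = dirs.nrow();
  double blo[3], bhi[3];
  for (int a = 0; a < 3; ++a) {
    blo[a] = (roi_lo[a] - 0.5) * spacing[a];
    bhi[a] = (roi_hi[a] + 0.5) * spacing[a];
  }
  const double eps = 1e-9 * (spacing[0] + spacing[1] + spacing[2]);
  NumericVector total_len(ndir);
  IntegerVector crossings(ndir);

  for (int j = 0; j < ndir; ++j) {
    double d[3] = {dirs(j, 0), dirs(j, 1), dirs(j, 2)};
    double len = 0.0;
    long cross = 0;
    for (int k = 0; k < npts; ++k) {
      double p[3] = {points(k, 0), points(k, 1), points(k, 2)};
      // slab intersection of the infinite line with the ROI box
      double tmin = -1e300, tmax = 1e300;
      bool miss = false;
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(d[a]) < 1e-300) {
          if (p[a] < blo[a] || p[a] > bhi[a]) { miss = true; break; }
        } else {
          double t1 = (blo[a] - p[a]) / d[a];
          double t2 = (bhi[a] - p[a]) / d[a];
          if (t1 > t2) std::swap(t1, t2);
          if (t1 > tmin) tmin = t1;
          if (t2 < tmax) tmax = t2;
        }
      }
      if (miss || tmax <= tmin) continue;
      len += tmax - tmin;

      // initial voxel just inside the entry face
      double t = tmin + eps;
      int iv[3];
      for (int a = 0; a < 3; ++a) {
        iv[a] = (int)std::floor((p[a] + t * d[a]) / spacing[a] + 0.5);
        if (iv[a] < roi_lo[a]) iv[a] = roi_lo[a];
        if (iv[a] > roi_hi[a]) iv[a] = roi_hi[a];
      }
      double tMax[3], tDelta[3];
      int step[3];
      for (int a = 0; a < 3; ++a) {
        if (d[a] > 1e-300) {
          step[a] = 1;
          tMax[a] = ((iv[a] + 0.5) * spacing[a] - p[a]) / d[a];
          tDelta[a] = spacing[a] / d[a];
        } else if (d[a] < -1e-300) {
          step[a] = -1;
          tMax[a] = ((iv[a] - 0.5) * spacing[a] - p[a]) / d[a];
          tDelta[a] = -spacing[a] / d[a];
        } else {
          step[a] = 0;
          tMax[a] = 1e300;
          tDelta[a] = 1e300;
        }
      }
      int prev = vol[iv[0] + nx * (iv[1] + (long)ny * iv[2])] ? 1 : 0;
      for (;;) {
        int a = 0;
        if (tMax[1] < tMax[a]) a = 1;
        if (tMax[2] < tMax[a]) a = 2;
        if (tMax[a] >= tmax - eps) break;
        iv[a] += step[a];
        if (iv[a] < roi_lo[a] || iv[a] > roi_hi[a]) break;
        tMax[a] += tDelta[a];
        int cur = vol[iv[0] + nx * (iv[1] + (long)ny * iv[2])] ? 1 : 0;
        if (cur != prev) ++cross;
        prev = cur;
      }
    }
    total_len[j] = len;
    crossings[j] = (int)cross;
  }
  return List::create(_["total_length_mm"] = total_len,
                      _["crossings"] = crossings);
}
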