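#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Accumulate per-voxel carving evidence for one view and one octree level.
//
// The active cells of the current level live on a dense index subgrid
// (nx x ny x nz cells of side `cell`, origin g0): idx[i] >= 0 gives the
// active-node number of a cell, -1 marks inactive cells. Each valid
// refracted ray (origin o, unit direction d, in-water extent [0, tmax]) is
// clipped to the subgrid box and walked with an Amanatides-Woo DDA; every
// active cell it crosses gets cover++ and, when the ray's silhouette pixel
// is foreground, hit++. The fraction hit/cover per node is the per-view
// visible fraction of that voxel.
//
// [[Rcpp::export(name = ".carve_accumulate_cpp")]]
List carve_accumulate_cpp(NumericVector ox, NumericVector oy, NumericVector oz,
                          NumericVector dx, NumericVector dy, NumericVector dz,
                          NumericVector tmax, LogicalVector fg,
                          IntegerVector idx,
                          int nx, int ny, int nz,
                          double gx0, double gy0, double gz0,
                          double cell, int n_active) {
  const R_xlen_t nray = ox.size();
  IntegerVector cover(n_active), hit(n_active);
  const double inf = std::numeric_limits<double>::infinity();
  const double gx1 = gx0 + nx * cell, gy1 = gy0 + ny * cell,
               gz1 = gz0 + nz * cell;

  for (R_xlen_t k = 0; k < nray; ++k) {
    const double o[3] = { ox[k], oy[k], oz[k] };
    const double d[3] = { dx[k], dy[k], dz[k] };
    const double g0[3] = { gx0, gy0, gz0 };
    const double g1[3] = { gx1, gy1, gz1 };
    const int n[3] = { nx, ny, nz };
    // clip [0, tmax] to the subgrid box
    double t0 = 0.0, t1 = tmax[k];
    bool miss = false;
    for (int ax = 0; ax < 3; ++ax) {
      if (std::fabs(d[ax]) < 1e-14) {
        if (o[ax] < g0[ax] || o[ax] > g1[ax]) { miss = true; break; }
      } else {
        double ta = (g0[ax] - o[ax]) / d[ax];
        double tb = (g1[ax] - o[ax]) / d[ax];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 > t1) { miss = true; break; }
      }
    }
    if (miss || t1 < t0) continue;
    // start cell (nudged inside the clipped range)
    const double tstart = t0 + 1e-12 * (1.0 + std::fabs(t0));
    int ci[3];
    for (int ax = 0; ax < 3; ++ax) {
      double p = o[ax] + d[ax] * tstart;
      int i = static_cast<int>(std::floor((p - g0[ax]) / cell));
      if (i < 0) i = 0;
      if (i >= n[ax]) i = n[ax] - 1;
      ci[ax] = i;
    }
    int stepi[3];
    double tDelta[3], tNext[3];
    for (int ax = 0; ax < 3; ++ax) {
      if (d[ax] > 1e-14) {
        stepi[ax] = 1;
        tDelta[ax] = cell / d[ax];
        tNext[ax] = (g0[ax] + (ci[ax] + 1) * cell - o[ax]) / d[ax];
      } else if (d[ax] < -1e-14) {
        stepi[ax] = -1;
        tDelta[ax] = -cell / d[ax];
        tNext[ax] = (g0[ax] + ci[ax] * cell - o[ax]) / d[ax];
      } else {
        stepi[ax] = 0;
        tDelta[ax] = inf;
        tNext[ax] = inf;
      }
    }
    const bool isfg = fg[k];
    double tcur = t0;
    while (tcur <= t1) {
      const int lin = ci[0] + nx * (ci[1] + ny * ci[2]);
      const int node = idx[lin];
      if (node >= 0) {
        ++cover[node];
        if (isfg) ++hit[node];
      }
      // advance to the next cell boundary
      int ax = 0;
      if (tNext[1] < tNext[ax]) ax = 1;
      if (tNext[2] < tNext[ax]) ax = 2;
      tcur = tNext[ax];
      ci[ax] += stepi[ax];
      if (ci[ax] < 0 || ci[ax] >= n[ax]) break;
      tNext[ax] += tDelta[ax];
    }
  }
  return List::create(_["cover"] = cover, _["hit"] = hit);
}
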