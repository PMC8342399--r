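#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline R_xlen_t idx3(int x, int y, int z, const int *d) {
  return (R_xlen_t)x + (R_xlen_t)d[0] * ((R_xlen_t)y + (R_xlen_t)d[1] * (R_xlen_t)z);
}

// Exhaustive integer-displacement block matching.
// A block of half-width `hw` centred on `pre_center` (0-based voxel indices) in
// `pre` is compared by NCC against blocks in `post` centred on
// `post_center + (dx,dy,dz)` for all displacements within `radius`.
// Tie-break: best NCC, then smallest |d|^2, then lexicographic (dx,dy,dz).
// status: 0 ok, 1 block shrunk at volume edge, 2 zero block variance (no score).
// [[Rcpp::export]]
List cpp_block_match(NumericVector pre, IntegerVector pdim,
                     NumericVector post, IntegerVector qdim,
                     IntegerVector pre_center, IntegerVector post_center,
                     int hw, int radius) {
  const int *pd = INTEGER(pdim);
  const int *qd = INTEGER(qdim);
  const double *pv = REAL(pre);
  const double *qv = REAL(post);

  // block extent relative to pre_center, clipped to pre bounds
  int lo[3], hi[3];
  bool shrunk = false;
  for (int a = 0; a < 3; ++a) {
    lo[a] = -hw;
    hi[a] = hw;
    if (pre_center[a] - hw < 0) { lo[a] = -pre_center[a]; shrunk = true; }
    if (pre_center[a] + hw > pd[a] - 1) { hi[a] = pd[a] - 1 - pre_center[a]; shrunk = true; }
    if (lo[a] > hi[a])
      return List::create(_["disp"] = IntegerVector::create(NA_INTEGER, NA_INTEGER, NA_INTEGER),
                          _["ncc"] = NA_REAL, _["status"] = 2);
  }

  // gather block values and moments
  std::vector<double> bv;
  bv.reserve((hi[0] - lo[0] + 1) * (hi[1] - lo[1] + 1) * (hi[2] - lo[2] + 1));
  double sb = 0, sbb = 0;
  for (int dz = lo[2]; dz <= hi[2]; ++dz)
    for (int dy = lo[1]; dy <= hi[1]; ++dy)
      for (int dx = lo[0]; dx <= hi[0]; ++dx) {
        const double v = pv[idx3(pre_center[0] + dx, pre_center[1] + dy,
                                 pre_center[2] + dz, pd)];
        bv.push_back(v);
        sb += v; sbb += v * v;
      }
  const R_xlen_t nb = (R_xlen_t)bv.size();
  const double varb = sbb - sb * sb / nb;
  if (!(varb > 0))
    return List::create(_["disp"] = IntegerVector::create(NA_INTEGER, NA_INTEGER, NA_INTEGER),
                        _["ncc"] = NA_REAL, _["status"] = 2);

  double best = -2.0;
  int bestd[3] = {0, 0, 0};
  long best_mag = -1;
  bool found = false;
  const int side = 2 * radius + 1;
  std::vector<double> grid((size_t)side * side * side, NA_REAL);

  for (int sz = -radius; sz <= radius; ++sz)
    for (int sy = -radius; sy <= radius; ++sy)
      for (int sx = -radius; sx <= radius; ++sx) {
        const int cx = post_center[0] + sx, cy = post_center[1] + sy,
                  cz = post_center[2] + sz;
        if (cx + lo[0] < 0 || cy + lo[1] < 0 || cz + lo[2] < 0 ||
            cx + hi[0] > qd[0] - 1 || cy + hi[1] > qd[1] - 1 || cz + hi[2] > qd[2] - 1)
          continue;
        double sq = 0, sqq = 0, sbq = 0;
        R_xlen_t k = 0;
        for (int dz = lo[2]; dz <= hi[2]; ++dz)
          for (int dy = lo[1]; dy <= hi[1]; ++dy) {
            R_xlen_t base = idx3(cx + lo[0], cy + dy, cz + dz, qd);
            for (int dx = lo[0]; dx <= hi[0]; ++dx, ++k) {
              const double v = qv[base + (dx - lo[0])];
              sq += v; sqq += v * v; sbq += bv[k] * v;
            }
          }
        const double varq = sqq - sq * sq / nb;
        if (!(varq > 0)) continue;
        const double ncc = (sbq - sb * sq / nb) / std::sqrt(varb * varq);
        grid[(size_t)(sx + radius) +
             (size_t)side * ((size_t)(sy + radius) +
                             (size_t)side * (size_t)(sz + radius))] = ncc;
        const long mag = (long)sx * sx + (long)sy * sy + (long)sz * sz;
        bool better = false;
        if (!found || ncc > best + 1e-12) {
          better = true;
        } else if (std::fabs(ncc - best) <= 1e-12) {
          if (mag < best_mag) better = true;
          else if (mag == best_mag) {
            if (sx < bestd[0] ||
                (sx == bestd[0] && (sy < bestd[1] ||
                                    (sy == bestd[1] && sz < bestd[2]))))
              better = true;
          }
        }
        if (better) {
          found = true;
          best = ncc;
          best_mag = mag;
          bestd[0] = sx; bestd[1] = sy; bestd[2] = sz;
        }
      }

  if (!found)
    return List::create(_["disp"] = IntegerVector::create(NA_INTEGER, NA_INTEGER, NA_INTEGER),
                        _["ncc"] = NA_REAL, _["status"] = 2);

  // sub-voxel refinement: 3-point parabola through the NCC peak per axis
  NumericVector subvox(3);
  for (int a = 0; a < 3; ++a) {
    int c[3] = {bestd[0] + radius, bestd[1] + radius, bestd[2] + radius};
    double off = 0.0;
    if (c[a] > 0 && c[a] < side - 1) {
      int lo_[3] = {c[0], c[1], c[2]}, hi_[3] = {c[0], c[1], c[2]};
      lo_[a] -= 1; hi_[a] += 1;
      const double nlo = grid[(size_t)lo_[0] + (size_t)side * ((size_t)lo_[1] + (size_t)side * lo_[2])];
      const double nhi = grid[(size_t)hi_[0] + (size_t)side * ((size_t)hi_[1] + (size_t)side * hi_[2])];
      const double nc = best;
      if (R_finite(nlo) && R_finite(nhi)) {
        const double denom = nlo - 2.0 * nc + nhi;
        if (denom < -1e-12) {
          off = 0.5 * (nlo - nhi) / denom;
          if (off > 0.5) off = 0.5;
          if (off < -0.5) off = -0.5;
        }
      }
    }
    subvox[a] = bestd[a] + off;
  }
  return List::create(
      _["disp"] = IntegerVector::create(bestd[0], bestd[1], bestd[2]),
      _["subvoxel"] = subvox,
      _["ncc"] = best, _["status"] = shrunk ? 1 : 0);
}
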