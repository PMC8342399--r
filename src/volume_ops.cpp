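#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel-index convention throughout: 0-based continuous coordinates, voxel i
// centred at index i. World mapping (origin + (i + 0.5) * voxel_size) is done
// on the R side; C++ only ever sees index coordinates.

static inline R_xlen_t idx3(int x, int y, int z, const int *d) {
  return (R_xlen_t)x + (R_xlen_t)d[0] * ((R_xlen_t)y + (R_xlen_t)d[1] * (R_xlen_t)z);
}

// Anti-aliased rendering of spheres by sub-sampled voxel coverage.
// centers: n x 3 (continuous voxel indices); radii in voxels.
// Each covered voxel is blended toward `attenuation` by its coverage fraction.
// Returns number of spheres that touched at least one voxel.
// [[Rcpp::export]]
int cpp_rasterize_spheres(NumericVector vol, IntegerVector dim,
                          NumericMatrix centers, NumericVector radii,
                          NumericVector attenuation, int supersampling) {
  const int *d = INTEGER(dim);
  const int m = supersampling;
  const double inv_m3 = 1.0 / ((double)m * m * m);
  // half-diagonal of a unit voxel: any voxel centre farther than r + this is
  // fully outside, closer than r - this fully inside
  const double hd = 0.8660254037844386;
  int touched_count = 0;

  std::vector<double> offs(m);
  for (int j = 0; j < m; ++j) offs[j] = (j + 0.5) / m - 0.5;

  for (int s = 0; s < centers.nrow(); ++s) {
    const double cx = centers(s, 0), cy = centers(s, 1), cz = centers(s, 2);
    const double r = radii[s], att = attenuation[s];
    const double r2 = r * r;
    bool touched = false;
    int x0 = std::max(0, (int)std::floor(cx - r - 1.0));
    int x1 = std::min(d[0] - 1, (int)std::ceil(cx + r + 1.0));
    int y0 = std::max(0, (int)std::floor(cy - r - 1.0));
    int y1 = std::min(d[1] - 1, (int)std::ceil(cy + r + 1.0));
    int z0 = std::max(0, (int)std::floor(cz - r - 1.0));
    int z1 = std::min(d[2] - 1, (int)std::ceil(cz + r + 1.0));
    for (int z = z0; z <= z1; ++z) {
      for (int y = y0; y <= y1; ++y) {
        for (int x = x0; x <= x1; ++x) {
          const double dx = x - cx, dy = y - cy, dz = z - cz;
          const double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
          double f;
          if (dist > r + hd) continue;
          if (dist < r - hd) {
            f = 1.0;
          } else {
            int cnt = 0;
            for (int a = 0; a < m; ++a)
              for (int b = 0; b < m; ++b)
                for (int c = 0; c < m; ++c) {
                  const double ddx = dx + offs[a], ddy = dy + offs[b], ddz = dz + offs[c];
                  if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) ++cnt;
                }
            if (cnt == 0) continue;
            f = cnt * inv_m3;
          }
          const R_xlen_t i = idx3(x, y, z, d);
          vol[i] = vol[i] * (1.0 - f) + att * f;
          touched = true;
        }
      }
    }
    if (touched) ++touched_count;
  }
  return touched_count;
}

// Connected-component labelling of a 3D binary mask (6- or 26-connectivity),
// iterative flood fill. Labels are 1..n in first-encounter (column-major) order.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int *d = INTEGER(dim);
  const R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  IntegerVector lab(n, 0);
  const int *mk = LOGICAL(mask);

  // neighbour offsets
  std::vector<int> nx, ny, nz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        nx.push_back(dx); ny.push_back(dy); nz.push_back(dz);
      }
  const int nn = (int)nx.size();

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        const R_xlen_t i0 = idx3(x, y, z, d);
        if (mk[i0] != TRUE || lab[i0] != 0) continue;
        ++next;
        lab[i0] = next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          const R_xlen_t i = stack.back();
          stack.pop_back();
          const int zz = (int)(i / ((R_xlen_t)d[0] * d[1]));
          const int rem = (int)(i - (R_xlen_t)zz * d[0] * d[1]);
          const int yy = rem / d[0];
          const int xx = rem - yy * d[0];
          for (int k = 0; k < nn; ++k) {
            const int ax = xx + nx[k], ay = yy + ny[k], az = zz + nz[k];
            if (ax < 0 || ay < 0 || az < 0 || ax >= d[0] || ay >= d[1] || az >= d[2]) continue;
            const R_xlen_t j = idx3(ax, ay, az, d);
            if (mk[j] == TRUE && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  lab.attr("n_components") = next;
  return lab;
}

static inline bool trilinear(const double *v, const int *d,
                             double x, double y, double z, double *out) {
  if (x < 0 || y < 0 || z < 0 || x > d[0] - 1 || y > d[1] - 1 || z > d[2] - 1)
    return false;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == d[0] - 1) --x0;
  if (y0 == d[1] - 1) --y0;
  if (z0 == d[2] - 1) --z0;
  if (d[0] == 1) x0 = 0;
  if (d[1] == 1) y0 = 0;
  if (d[2] == 1) z0 = 0;
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  const int x1 = std::min(x0 + 1, d[0] - 1), y1 = std::min(y0 + 1, d[1] - 1),
            z1 = std::min(z0 + 1, d[2] - 1);
  const double c000 = v[idx3(x0, y0, z0, d)], c100 = v[idx3(x1, y0, z0, d)];
  const double c010 = v[idx3(x0, y1, z0, d)], c110 = v[idx3(x1, y1, z0, d)];
  const double c001 = v[idx3(x0, y0, z1, d)], c101 = v[idx3(x1, y0, z1, d)];
  const double c011 = v[idx3(x0, y1, z1, d)], c111 = v[idx3(x1, y1, z1, d)];
  const double c00 = c000 * (1 - fx) + c100 * fx;
  const double c10 = c010 * (1 - fx) + c110 * fx;
  const double c01 = c001 * (1 - fx) + c101 * fx;
  const double c11 = c011 * (1 - fx) + c111 * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  *out = c0 * (1 - fz) + c1 * fz;
  return true;
}

// Catmull-Rom cubic kernel
static inline double cr_w(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

static inline bool tricubic(const double *v, const int *d,
                            double x, double y, double z, double *out) {
  if (x < 0 || y < 0 || z < 0 || x > d[0] - 1 || y > d[1] - 1 || z > d[2] - 1)
    return false;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double acc = 0.0, wsum = 0.0;
  for (int k = -1; k <= 2; ++k) {
    int zz = std::min(std::max(z0 + k, 0), d[2] - 1);
    const double wz = cr_w(z - (z0 + k));
    if (wz == 0.0) continue;
    for (int j = -1; j <= 2; ++j) {
      int yy = std::min(std::max(y0 + j, 0), d[1] - 1);
      const double wy = cr_w(y - (y0 + j));
      if (wy == 0.0) continue;
      for (int i = -1; i <= 2; ++i) {
        int xx = std::min(std::max(x0 + i, 0), d[0] - 1);
        const double wx = cr_w(x - (x0 + i));
        if (wx == 0.0) continue;
        const double w = wx * wy * wz;
        acc += w * v[idx3(xx, yy, zz, d)];
        wsum += w;
      }
    }
  }
  *out = acc / wsum;
  return true;
}

// Resample `mov` onto an output grid: output voxel p maps to moving-grid
// coordinate q = A p + b (both continuous voxel indices).
// method: 0 = nearest, 1 = trilinear, 3 = tricubic (Catmull-Rom).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector mov, IntegerVector mdim,
                                  IntegerVector outdim, NumericMatrix A,
                                  NumericVector b, double fill, int method) {
  const int *md = INTEGER(mdim);
  const int *od = INTEGER(outdim);
  const double *v = REAL(mov);
  const R_xlen_t n = (R_xlen_t)od[0] * od[1] * od[2];
  NumericVector out(n);
  R_xlen_t i = 0;
  for (int z = 0; z < od[2]; ++z)
    for (int y = 0; y < od[1]; ++y)
      for (int x = 0; x < od[0]; ++x, ++i) {
        const double qx = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + b[0];
        const double qy = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + b[1];
        const double qz = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + b[2];
        double val;
        bool ok;
        if (method == 0) {
          const int ix = (int)std::lround(qx), iy = (int)std::lround(qy),
                    iz = (int)std::lround(qz);
          ok = ix >= 0 && iy >= 0 && iz >= 0 && ix < md[0] && iy < md[1] && iz < md[2];
          if (ok) val = v[idx3(ix, iy, iz, md)];
        } else if (method == 3) {
          ok = tricubic(v, md, qx, qy, qz, &val);
        } else {
          ok = trilinear(v, md, qx, qy, qz, &val);
        }
        out[i] = ok ? val : fill;
      }
  return out;
}

// Normalized cross-correlation between fixed samples and the moving volume
// interpolated at q = A p + b for each fixed sample point p.
// pts: n x 3 fixed voxel coordinates; fvals: fixed intensities at pts.
// method: 1 = trilinear, 3 = tricubic (Catmull-Rom; its flatter passband at
// fractional shifts avoids the integer-lattice bias of linear interpolation).
// [[Rcpp::export]]
List cpp_ncc_points(NumericVector fvals, NumericMatrix pts,
                    NumericVector mov, IntegerVector mdim,
                    NumericMatrix A, NumericVector b, int method = 1) {
  const int *md = INTEGER(mdim);
  const double *v = REAL(mov);
  const R_xlen_t n = pts.nrow();
  double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  R_xlen_t cnt = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    const double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + b[0];
    const double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + b[1];
    const double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + b[2];
    double mval;
    bool ok = (method == 3) ? tricubic(v, md, qx, qy, qz, &mval)
                            : trilinear(v, md, qx, qy, qz, &mval);
    if (!ok) continue;
    const double fv = fvals[i];
    sf += fv; sm += mval; sff += fv * fv; smm += mval * mval; sfm += fv * mval;
    ++cnt;
  }
  double ncc = NA_REAL;
  if (cnt > 1) {
    const double covfm = sfm - sf * sm / cnt;
    const double varf = sff - sf * sf / cnt;
    const double varm = smm - sm * sm / cnt;
    if (varf > 0 && varm > 0) ncc = covfm / std::sqrt(varf * varm);
  }
  return List::create(_["ncc"] = ncc, _["n"] = (double)cnt);
}

// Block-mean downsampling by an integer factor (edges truncated).
// [[Rcpp::export]]
NumericVector cpp_downsample(NumericVector vol, IntegerVector dim, int factor) {
  const int *d = INTEGER(dim);
  const int ox = d[0] / factor, oy = d[1] / factor, oz = d[2] / factor;
  const double *v = REAL(vol);
  NumericVector out((R_xlen_t)ox * oy * oz);
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  const double inv = 1.0 / ((double)factor * factor * factor);
  R_xlen_t i = 0;
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x, ++i) {
        double acc = 0;
        for (int c = 0; c < factor; ++c)
          for (int b2 = 0; b2 < factor; ++b2)
            for (int a = 0; a < factor; ++a)
              acc += v[idx3(x * factor + a, y * factor + b2, z * factor + c, d)];
        out[i] = acc * inv;
      }
  return out;
}

// Separable Gaussian smoothing, truncated at 3 sigma (sigma in voxels).
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim, double sigma) {
  const int *d = INTEGER(dim);
  const R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  if (sigma <= 0) return clone(vol);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double ks = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    ks += k[i + rad];
  }
  for (auto &w : k) w /= ks;

  NumericVector a = clone(vol);
  NumericVector tmp(n);
  const int dims[3] = {d[0], d[1], d[2]};
  // pass along each axis with edge clamping
  for (int axis = 0; axis < 3; ++axis) {
    double *src = REAL(a), *dst = REAL(tmp);
    for (int z = 0; z < dims[2]; ++z)
      for (int y = 0; y < dims[1]; ++y)
        for (int x = 0; x < dims[0]; ++x) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int xx = x, yy = y, zz = z;
            if (axis == 0) xx = std::min(std::max(x + t, 0), dims[0] - 1);
            else if (axis == 1) yy = std::min(std::max(y + t, 0), dims[1] - 1);
            else zz = std::min(std::max(z + t, 0), dims[2] - 1);
            acc += k[t + rad] * src[idx3(xx, yy, zz, dims)];
          }
          dst[idx3(x, y, z, dims)] = acc;
        }
    std::swap(a, tmp);
  }
  a.attr("dim") = dim;
  return a;
}
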