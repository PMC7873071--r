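#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-segment straight-ray delay through an axis-aligned half ellipsoid.
// Tissue region: (x/a)^2 + (y/b)^2 + ((z-z0)/cz)^2 <= 1 AND z <= z0.
// Returns delay in us for the ray from e (element) to v (voxel).
static double dual_delay(const double *v, const double *e,
                         double a, double b, double cz, double z0,
                         double c_tissue, double c_water) {
  double dx = v[0] - e[0], dy = v[1] - e[1], dz = v[2] - e[2];
  double len = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (len <= 0.0) return NA_REAL;
  // Parametrize p(s) = e + s * (v - e), s in [0, 1].
  // Ellipsoid intersection: quadratic in s.
  double ex = e[0] / a, ey = e[1] / b, ez = (e[2] - z0) / cz;
  double rx = dx / a, ry = dy / b, rz = dz / cz;
  double A = rx * rx + ry * ry + rz * rz;
  double B = 2.0 * (ex * rx + ey * ry + ez * rz);
  double C = ex * ex + ey * ey + ez * ez - 1.0;
  double s0 = 1.0, s1 = 0.0; // empty interval by default
  if (A > 0.0) {
    double disc = B * B - 4.0 * A * C;
    if (disc > 0.0) {
      double sq = std::sqrt(disc);
      s0 = (-B - sq) / (2.0 * A);
      s1 = (-B + sq) / (2.0 * A);
    }
  }
  // Clip to the lower half-space z <= z0: e_z + s*dz <= z0.
  double h0 = 0.0, h1 = 1.0;
  if (std::abs(dz) < 1e-300) {
    if (e[2] > z0) { h0 = 1.0; h1 = 0.0; }
  } else {
    double sc = (z0 - e[2]) / dz;
    if (dz > 0) { h1 = std::min(1.0, sc); }
    else        { h0 = std::max(0.0, sc); }
  }
  double lo = std::max(std::max(s0, h0), 0.0);
  double hi = std::min(std::min(s1, h1), 1.0);
  double frac = (hi > lo) ? (hi - lo) : 0.0;
  double L_tissue = frac * len;
  double L_water = len - L_tissue;
  return L_tissue / c_tissue + L_water / c_water;
}

// [[Rcpp::export(name = ".ubp_core")]]
NumericVector ubp_core(NumericMatrix bmat,      // T x P filtered terms b(t)
                       NumericMatrix det_pos,   // P x 3 poses (mm)
                       NumericMatrix det_nrm,   // P x 3 unit normals
                       NumericVector grid_dim,  // nx, ny, nz
                       NumericVector origin,    // mm (center of voxel [1,1,1])
                       double voxel,            // mm
                       double t0, double dt,    // us
                       double c_water, double c_tissue,
                       NumericVector ellipsoid, // len 0 or 4: a, b, cz, z0
                       bool linear_interp,
                       NumericVector pose_w) {  // per-pose quadrature weight
  const int T = bmat.nrow(), P = bmat.ncol();
  const int nx = (int)grid_dim[0], ny = (int)grid_dim[1],
            nz = (int)grid_dim[2];
  const bool dual = ellipsoid.size() == 4;
  const double ea = dual ? ellipsoid[0] : 0.0,
               eb = dual ? ellipsoid[1] : 0.0,
               ec = dual ? ellipsoid[2] : 0.0,
               ez0 = dual ? ellipsoid[3] : 0.0;
  NumericVector out((R_xlen_t)nx * ny * nz);
  NumericVector wsum((R_xlen_t)nx * ny * nz);
  long long skipped = 0;
  double v[3];
  const bool has_pw = pose_w.size() == P;
  for (int p = 0; p < P; ++p) {
    const double pw = has_pw ? pose_w[p] : 1.0;
    if (pw <= 0.0) continue;
    const double px = det_pos(p, 0), py = det_pos(p, 1), pz = det_pos(p, 2);
    const double nxv = det_nrm(p, 0), nyv = det_nrm(p, 1),
                 nzv = det_nrm(p, 2);
    const double *bcol = &bmat(0, p);
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      const double vz = origin[2] + k * voxel;
      for (int j = 0; j < ny; ++j) {
        const double vy = origin[1] + j * voxel;
        for (int i = 0; i < nx; ++i, ++idx) {
          const double vx = origin[0] + i * voxel;
          const double dx = vx - px, dy = vy - py, dz = vz - pz;
          const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d <= 0.0) continue;
          double tau;
          if (dual) {
            v[0] = vx; v[1] = vy; v[2] = vz;
            const double e[3] = {px, py, pz};
            tau = dual_delay(v, e, ea, eb, ec, ez0, c_tissue, c_water);
          } else {
            tau = d / c_water;
          }
          const double ts = (tau - t0) / dt; // fractional sample index
          if (ts < 0.0 || ts > T - 1) { ++skipped; continue; }
          double bval;
          if (linear_interp) {
            const int i0 = (int)std::floor(ts);
            const int i1 = (i0 + 1 < T) ? i0 + 1 : i0;
            const double f = ts - i0;
            bval = (1.0 - f) * bcol[i0] + f * bcol[i1];
          } else {
            bval = bcol[(int)std::lround(ts)];
          }
          // solid-angle weight: cos(theta) / d^2 (aperture area constant,
          // cancels in the per-voxel normalization)
          double cth = (dx * nxv + dy * nyv + dz * nzv) / d;
          if (cth < 0.0) cth = 0.0;
          const double w = pw * cth / (d * d);
          out[idx] += w * bval;
          wsum[idx] += w;
        }
      }
    }
  }
  for (R_xlen_t q = 0; q < out.size(); ++q)
    if (wsum[q] > 0.0) out[q] /= wsum[q];
  out.attr("skipped") = (double)skipped;
  return out;
}

// [[Rcpp::export(name = ".dual_delay_cpp")]]
NumericVector dual_delay_cpp(NumericMatrix voxels, NumericMatrix elements,
                             double a, double b, double cz, double z0,
                             double c_tissue, double c_water) {
  const int n = voxels.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double v[3] = {voxels(i, 0), voxels(i, 1), voxels(i, 2)};
    const double e[3] = {elements(i, 0), elements(i, 1), elements(i, 2)};
    out[i] = dual_delay(v, e, a, b, cz, z0, c_tissue, c_water);
  }
  return out;
}
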