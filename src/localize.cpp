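#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Summed pairwise DToA mismatch at a candidate point.
// times: corrected arrival times of the group's detections
// sx/sy/sz: station coordinates per detection
static double dtoa_error(double px, double py, double pz,
                         const double *times, const double *sx,
                         const double *sy, const double *sz,
                         int k, double c, bool use_sq) {
  double d[64];
  if (k > 64) k = 64;
  for (int i = 0; i < k; ++i) {
    double dx = px - sx[i], dy = py - sy[i], dz = pz - sz[i];
    d[i] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  double err = 0.0;
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j) {
      double e = (times[i] - times[j]) - (d[i] - d[j]) / c;
      err += use_sq ? e * e : std::fabs(e);
    }
  return err;
}

// Grid argmin over [x0,x1] x [y0,y1] at the given spacing.
static void grid_argmin(double x0, double x1, double y0, double y1,
                        double spacing, double pz,
                        const double *times, const double *sx,
                        const double *sy, const double *sz, int k,
                        double c, bool use_sq,
                        double &bx, double &by, double &be) {
  int nx = (int)std::floor((x1 - x0) / spacing) + 1;
  int ny = (int)std::floor((y1 - y0) / spacing) + 1;
  be = std::numeric_limits<double>::infinity();
  for (int iy = 0; iy < ny; ++iy) {
    double py = y0 + iy * spacing;
    for (int ix = 0; ix < nx; ++ix) {
      double px = x0 + ix * spacing;
      double e = dtoa_error(px, py, pz, times, sx, sy, sz, k, c, use_sq);
      if (e < be) { be = e; bx = px; by = py; }
    }
  }
}

// Batch DToA localization: coarse-to-fine grid search with a final
// one-dimensional quadratic (3-point parabola) refinement per axis.
//
// times, sx, sy, sz: concatenated over groups; grp_ptr (0-based, length
// n_groups+1) delimits each group; zt: tag depth per group.
// Returns an n_groups x 3 matrix (x, y, residual).
// [[Rcpp::export]]
NumericMatrix cpp_localize_batch(NumericVector times, NumericVector sx,
                                 NumericVector sy, NumericVector sz,
                                 IntegerVector grp_ptr, NumericVector zt,
                                 double xmin, double xmax, double ymin,
                                 double ymax, double spacing,
                                 int coarse_factor, double c_sound,
                                 bool use_sq) {
  int ng = grp_ptr.size() - 1;
  NumericMatrix out(ng, 3);
  double coarse = spacing * std::max(coarse_factor, 1);

  for (int g = 0; g < ng; ++g) {
    int a = grp_ptr[g], b = grp_ptr[g + 1];
    int k = b - a;
    const double *t = &times[a], *px = &sx[a], *py = &sy[a], *pz = &sz[a];
    double z = zt[g];
    double bx, by, be;

    grid_argmin(xmin, xmax, ymin, ymax, coarse, z,
                t, px, py, pz, k, c_sound, use_sq, bx, by, be);
    if (coarse_factor > 1) {
      double fx0 = std::max(xmin, bx - 2 * coarse);
      double fx1 = std::min(xmax, bx + 2 * coarse);
      double fy0 = std::max(ymin, by - 2 * coarse);
      double fy1 = std::min(ymax, by + 2 * coarse);
      grid_argmin(fx0, fx1, fy0, fy1, spacing, z,
                  t, px, py, pz, k, c_sound, use_sq, bx, by, be);
    }

    // quadratic refinement within half a cell on each axis
    double h = spacing;
    double exm = dtoa_error(bx - h, by, z, t, px, py, pz, k, c_sound, use_sq);
    double exp_ = dtoa_error(bx + h, by, z, t, px, py, pz, k, c_sound, use_sq);
    double den = exm - 2 * be + exp_;
    double rx = bx;
    if (den > 1e-15) {
      double off = 0.5 * (exm - exp_) / den * h;
      if (off > h / 2) off = h / 2; if (off < -h / 2) off = -h / 2;
      rx = bx + off;
    }
    double eym = dtoa_error(bx, by - h, z, t, px, py, pz, k, c_sound, use_sq);
    double eyp = dtoa_error(bx, by + h, z, t, px, py, pz, k, c_sound, use_sq);
    den = eym - 2 * be + eyp;
    double ry = by;
    if (den > 1e-15) {
      double off = 0.5 * (eym - eyp) / den * h;
      if (off > h / 2) off = h / 2; if (off < -h / 2) off = -h / 2;
      ry = by + off;
    }
    double re = dtoa_error(rx, ry, z, t, px, py, pz, k, c_sound, use_sq);
    if (re > be) { rx = bx; ry = by; re = be; }

    out(g, 0) = rx; out(g, 1) = ry; out(g, 2) = re;
  }
  return out;
}
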