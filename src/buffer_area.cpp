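#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact area of the intersection between a disc and an axis-aligned
// rectangle, used for area-weighted buffer-zone means (zonal statistics).
// All geometry is expressed in coordinates relative to the disc centre.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Integral of sqrt(r^2 - u^2) du over [a, b], arguments clamped to [-r, r].
static double chord_integral(double a, double b, double r) {
  a = clampd(a, -r, r);
  b = clampd(b, -r, r);
  if (b <= a) return 0.0;
  auto F = [r](double u) {
    double s2 = r * r - u * u;
    double s = s2 > 0.0 ? std::sqrt(s2) : 0.0;
    return 0.5 * (u * s + r * r * std::asin(clampd(u / r, -1.0, 1.0)));
  };
  return F(b) - F(a);
}

// Area of {(u,v): u <= x, v <= y} intersected with the disc of radius r
// centred at the origin.
static double corner_area(double x, double y, double r) {
  if (x <= -r || y <= -r) return 0.0;
  double xc = std::min(x, r);
  double yc = std::min(y, r);
  if (yc >= r) return 2.0 * chord_integral(-r, xc, r);
  double w = std::sqrt(std::max(0.0, r * r - yc * yc));
  if (yc >= 0.0) {
    double area = 2.0 * chord_integral(-r, std::min(xc, -w), r);
    if (xc > -w) {
      double m = std::min(xc, w);
      area += chord_integral(-w, m, r) + yc * (m + w);
    }
    if (xc > w) area += 2.0 * chord_integral(w, xc, r);
    return area;
  }
  double m = std::min(xc, w);
  if (m <= -w) return 0.0;
  return chord_integral(-w, m, r) + yc * (m + w);
}

// Area of the intersection of the disc (centre origin, radius r) with the
// rectangle [x1,x2] x [y1,y2] via inclusion-exclusion of corner areas.
static double disc_rect_area(double x1, double x2, double y1, double y2,
                             double r) {
  double a = corner_area(x2, y2, r) - corner_area(x1, y2, r) -
             corner_area(x2, y1, r) + corner_area(x1, y1, r);
  return a > 0.0 ? a : 0.0;
}

// Area-weighted mean of raster values within a disc, one disc per centre.
// values: matrix with row 1 = top of the raster; NA marks nodata.
// origin_x/origin_y: planar coordinates of the upper-left raster corner.
// Nodata pixels and off-raster area are excluded from numerator and
// denominator (coverage renormalisation). Returns NA when the disc covers
// no valid pixel area.
// [[Rcpp::export]]
NumericVector cpp_buffer_mean(NumericMatrix values, double origin_x,
                              double origin_y, double pixel,
                              NumericVector cx, NumericVector cy,
                              double radius) {
  const int nr = values.nrow(), nc = values.ncol();
  const int npts = cx.size();
  NumericVector out(npts);
  const double r2 = radius * radius;
  const double full = pixel * pixel;

  for (int k = 0; k < npts; ++k) {
    const double x0 = cx[k], y0 = cy[k];
    // candidate pixel index ranges (1-based rows from top, cols from left)
    int i_lo = (int)std::floor((origin_y - (y0 + radius)) / pixel) + 1;
    int i_hi = (int)std::floor((origin_y - (y0 - radius)) / pixel) + 1;
    int j_lo = (int)std::floor((x0 - radius - origin_x) / pixel) + 1;
    int j_hi = (int)std::floor((x0 + radius - origin_x) / pixel) + 1;
    if (i_lo < 1) i_lo = 1;
    if (j_lo < 1) j_lo = 1;
    if (i_hi > nr) i_hi = nr;
    if (j_hi > nc) j_hi = nc;

    double wsum = 0.0, asum = 0.0;
    for (int i = i_lo; i <= i_hi; ++i) {
      const double y2v = origin_y - (i - 1) * pixel - y0;  // pixel top
      const double y1v = y2v - pixel;                      // pixel bottom
      // nearest/farthest vertical offsets to the disc centre
      const double ny = (y1v > 0.0) ? y1v : ((y2v < 0.0) ? -y2v : 0.0);
      const double fy = std::max(std::fabs(y1v), std::fabs(y2v));
      for (int j = j_lo; j <= j_hi; ++j) {
        const double v = values(i - 1, j - 1);
        if (ISNAN(v)) continue;
        const double x1v = origin_x + (j - 1) * pixel - x0;
        const double x2v = x1v + pixel;
        const double nx = (x1v > 0.0) ? x1v : ((x2v < 0.0) ? -x2v : 0.0);
        if (nx * nx + ny * ny >= r2) continue;  // entirely outside
        const double fx = std::max(std::fabs(x1v), std::fabs(x2v));
        double a;
        if (fx * fx + fy * fy <= r2) {
          a = full;  // entirely inside
        } else {
          a = disc_rect_area(x1v, x2v, y1v, y2v, radius);
          if (a <= 0.0) continue;
        }
        wsum += a * v;
        asum += a;
      }
    }
    out[k] = (asum > 0.0) ? (wsum / asum) : NA_REAL;
  }
  return out;
}
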