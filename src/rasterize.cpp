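#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Even-odd ray-cast: is point (px,py) inside the polygon? Rightward ray,
// edge crossing when the endpoints straddle py and the intersection lies
// strictly right of px. Matches the scanline fill below by construction.
static bool point_in_poly(double px, double py,
                          const NumericVector& xs, const NumericVector& ys) {
  int n = xs.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if ((ys[i] > py) != (ys[j] > py)) {
      double xc = xs[j] + (py - ys[j]) * (xs[i] - xs[j]) / (ys[i] - ys[j]);
      if (px < xc) inside = !inside;
    }
  }
  return inside;
}

// [[Rcpp::export]]
bool cpp_point_in_poly(double px, double py, NumericVector xs, NumericVector ys) {
  return point_in_poly(px, py, xs, ys);
}

// Scanline even-odd fill of one polygon into an H x W mask (row-major R
// matrix, 0-based pixel indices). Pixel (r, c) is filled iff its center
// (c + 0.5, r + 0.5) is inside the polygon. Polygons are implicitly clipped
// to the image bounds.
static void fill_polygon(IntegerMatrix& mask,
                         const NumericVector& xs, const NumericVector& ys,
                         int value) {
  int H = mask.nrow(), W = mask.ncol();
  int n = xs.size();
  if (n < 3) return;
  double ymin = *std::min_element(ys.begin(), ys.end());
  double ymax = *std::max_element(ys.begin(), ys.end());
  int r0 = std::max(0, (int)std::floor(ymin - 0.5));
  int r1 = std::min(H - 1, (int)std::ceil(ymax));
  std::vector<double> xc;
  for (int r = r0; r <= r1; ++r) {
    double py = r + 0.5;
    xc.clear();
    for (int i = 0, j = n - 1; i < n; j = i++) {
      if ((ys[i] > py) != (ys[j] > py)) {
        xc.push_back(xs[j] + (py - ys[j]) * (xs[i] - xs[j]) / (ys[i] - ys[j]));
      }
    }
    std::sort(xc.begin(), xc.end());
    for (size_t k = 0; k + 1 < xc.size(); k += 2) {
      // fill columns with center in [xc[k], xc[k+1])
      int c0 = std::max(0, (int)std::ceil(xc[k] - 0.5));
      int c1 = std::min(W - 1, (int)std::ceil(xc[k + 1] - 0.5) - 1);
      for (int c = c0; c <= c1; ++c) mask(r, c) = value;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_polys(int height, int width, List polys) {
  IntegerMatrix mask(height, width);  // zero-initialized = background
  for (int k = 0; k < polys.size(); ++k) {
    List p = polys[k];
    NumericVector xs = p["x"], ys = p["y"];
    int value = as<int>(p["value"]);
    fill_polygon(mask, xs, ys, value);
  }
  return mask;
}

// Signed polygon area (shoelace); magnitude used to pick the smallest
// enclosing structure for lumina.
// [[Rcpp::export]]
double cpp_poly_area(NumericVector xs, NumericVector ys) {
  int n = xs.size();
  double a = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++)
    a += (xs[j] + xs[i]) * (ys[j] - ys[i]);
  return 0.5 * a;
}
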