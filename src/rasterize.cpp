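#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Scanline rasterization of a closed polygon under the even-odd rule.
// Pixel centers sit at x0 + (i - 0.5) * dx, y0 + (j - 0.5) * dy. The polygon
// may self-intersect; parity of edge crossings along each scanline handles
// that case by construction. Returns an nx x ny integer matrix of 0/1.
// [[Rcpp::export]]
IntegerMatrix fill_polygon_cpp(NumericVector px, NumericVector py,
                               int nx, int ny,
                               double x0, double y0, double dx, double dy) {
  int nv = px.size();
  IntegerMatrix out(nx, ny);
  std::vector<double> xs;
  xs.reserve(16);
  for (int j = 0; j < ny; j++) {
    double yc = y0 + (j + 0.5) * dy;
    xs.clear();
    for (int m = 0; m < nv; m++) {
      int m2 = (m + 1 == nv) ? 0 : m + 1;
      double y1 = py[m], y2 = py[m2];
      // half-open rule avoids double-counting shared vertices
      if ((y1 <= yc && yc < y2) || (y2 <= yc && yc < y1)) {
        double t = (yc - y1) / (y2 - y1);
        xs.push_back(px[m] + t * (px[m2] - px[m]));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t s = 0; s + 1 < xs.size(); s += 2) {
      double a = xs[s], b = xs[s + 1];
      // pixel centers strictly inside (a, b)
      int ilo = (int)std::floor((a - x0) / dx + 0.5);     // first i with xc > a
      int ihi = (int)std::ceil((b - x0) / dx - 0.5) - 1;  // last i with xc < b
      if (ilo < 0) ilo = 0;
      if (ihi > nx - 1) ihi = nx - 1;
      for (int i = ilo; i <= ihi; i++) {
        double xc = x0 + (i + 0.5) * dx;
        if (xc > a && xc < b) out(i, j) = 1;
      }
    }
  }
  return out;
}
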