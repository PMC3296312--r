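#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas).
// f: sampled function values; d: output; n: length. Exact for squared
// Euclidean distances, so the composed multi-axis transform is exact too.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

static void edt_squared_impl(NumericVector &g, int nx, int ny, int nz);

// Exact squared Euclidean distance (in index units, element centers) from
// every element to the nearest TRUE element of a 2D/3D logical array.
// Elements that are TRUE get 0; if no element is TRUE, all entries are Inf.
// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector feature, IntegerVector dims) {
  const double INF = std::numeric_limits<double>::infinity();
  int nd = dims.size();
  int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = feature[i] ? 0.0 : INF;
  edt_squared_impl(g, nx, ny, nz);
  return g;
}

// Signed Euclidean distance map: negative inside the foreground, positive
// outside, magnitude = distance to the nearest opposite-label element center.
// [[Rcpp::export]]
NumericVector edt_signed_cpp(LogicalVector fg, IntegerVector dims) {
  const double INF = std::numeric_limits<double>::infinity();
  int nd = dims.size();
  int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector to_fg(n), to_bg(n);
  for (R_xlen_t i = 0; i < n; i++) {
    to_fg[i] = fg[i] ? 0.0 : INF;
    to_bg[i] = fg[i] ? INF : 0.0;
  }
  edt_squared_impl(to_fg, nx, ny, nz);
  edt_squared_impl(to_bg, nx, ny, nz);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    out[i] = fg[i] ? -std::sqrt(to_bg[i]) : std::sqrt(to_fg[i]);
  }
  return out;
}

static void edt_squared_impl(NumericVector &g, int nx, int ny, int nz) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  (void)n;

  std::vector<double> f, d;

  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t off = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; x++) f[x] = g[off + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; x++) g[off + x] = d[x];
    }

  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * z;
      for (int y = 0; y < ny; y++) f[y] = g[base + (R_xlen_t)nx * y];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; y++) g[base + (R_xlen_t)nx * y] = d[y];
    }

  // pass along z
  if (nz > 1) {
    f.resize(nz); d.resize(nz);
    R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t base = x + (R_xlen_t)nx * y;
        for (int z = 0; z < nz; z++) f[z] = g[base + stride * z];
        dt1d(f, d, nz);
        for (int z = 0; z < nz; z++) g[base + stride * z] = d[z];
      }
  }
}
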