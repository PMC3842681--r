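#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// 1-D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher, lower envelope of parabolas), with anisotropic spacing:
// d[q] = min_p ( w2 * (q - p)^2 + f[p] ),   w2 = spacing^2 along the axis.
// Exact in exact arithmetic; stride-aware so it runs along any array axis.
static void dt1d(const double *f, double *d, int *v, double *z,
                 int n, double w2) {
  const double INF = 1e30;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      const int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Euclidean distance (mm) from every voxel centre to the nearest TRUE
// voxel centre. Column-major 3-D array, physical spacing per axis.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector fg, IntegerVector dims,
                      NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t total = (R_xlen_t)n1 * n2 * n3;
  if (fg.size() != total)
    stop("mask length does not match dims");
  const double INF = 1e30;

  std::vector<double> sq(total);
  bool any = false;
  for (R_xlen_t i = 0; i < total; ++i) {
    sq[i] = fg[i] ? 0.0 : INF;
    if (fg[i]) any = true;
  }
  if (!any) stop("distance transform of an all-false mask");

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> fbuf(nmax), dbuf(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along axis 1 (stride 1)
  for (int k3 = 0; k3 < n3; ++k3)
    for (int k2 = 0; k2 < n2; ++k2) {
      double *col = sq.data() + (R_xlen_t)n1 * (k2 + (R_xlen_t)n2 * k3);
      dt1d(col, dbuf.data(), v.data(), z.data(), n1,
           spacing[0] * spacing[0]);
      std::copy(dbuf.begin(), dbuf.begin() + n1, col);
    }
  // pass along axis 2 (stride n1)
  for (int k3 = 0; k3 < n3; ++k3)
    for (int k1 = 0; k1 < n1; ++k1) {
      double *base = sq.data() + k1 + (R_xlen_t)n1 * n2 * k3;
      for (int q = 0; q < n2; ++q) fbuf[q] = base[(R_xlen_t)n1 * q];
      dt1d(fbuf.data(), dbuf.data(), v.data(), z.data(), n2,
           spacing[1] * spacing[1]);
      for (int q = 0; q < n2; ++q) base[(R_xlen_t)n1 * q] = dbuf[q];
    }
  // pass along axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int k2 = 0; k2 < n2; ++k2)
    for (int k1 = 0; k1 < n1; ++k1) {
      double *base = sq.data() + k1 + (R_xlen_t)n1 * k2;
      for (int q = 0; q < n3; ++q) fbuf[q] = base[s3 * q];
      dt1d(fbuf.data(), dbuf.data(), v.data(), z.data(), n3,
           spacing[2] * spacing[2]);
      for (int q = 0; q < n3; ++q) base[s3 * q] = dbuf[q];
    }

  NumericVector out(total);
  for (R_xlen_t i = 0; i < total; ++i) out[i] = std::sqrt(sq[i]);
  out.attr("dim") = dims;
  return out;
}

// Trilinear interpolation of a column-major 3-D array at continuous
// 0-based index coordinates; samples outside the grid get `fill`.
// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector arr, IntegerVector dims,
                            NumericVector xi, NumericVector yi,
                            NumericVector zi, double fill) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  if (arr.size() != (R_xlen_t)n1 * n2 * n3)
    stop("array length does not match dims");
  const R_xlen_t n = xi.size();
  if (yi.size() != n || zi.size() != n)
    stop("coordinate vectors differ in length");
  NumericVector out(n);
  const double *a = arr.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = xi[p], y = yi[p], z = zi[p];
    if (!(x >= 0.0) || !(y >= 0.0) || !(z >= 0.0) ||
        x > n1 - 1.0 || y > n2 - 1.0 || z > n3 - 1.0) {
      out[p] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 == n1 - 1) --x0;
    if (y0 == n2 - 1) --y0;
    if (z0 == n3 - 1) --z0;
    if (n1 == 1) x0 = 0;
    if (n2 == 1) y0 = 0;
    if (n3 == 1) z0 = 0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const int x1 = std::min(x0 + 1, n1 - 1);
    const int y1 = std::min(y0 + 1, n2 - 1);
    const int z1 = std::min(z0 + 1, n3 - 1);
#define IDX(i, j, k) ((R_xlen_t)(i) + (R_xlen_t)n1 * ((j) + (R_xlen_t)n2 * (k)))
    const double c000 = a[IDX(x0, y0, z0)], c100 = a[IDX(x1, y0, z0)];
    const double c010 = a[IDX(x0, y1, z0)], c110 = a[IDX(x1, y1, z0)];
    const double c001 = a[IDX(x0, y0, z1)], c101 = a[IDX(x1, y0, z1)];
    const double c011 = a[IDX(x0, y1, z1)], c111 = a[IDX(x1, y1, z1)];
#undef IDX
    const double c00 = c000 * (1 - fx) + c100 * fx;
    const double c10 = c010 * (1 - fx) + c110 * fx;
    const double c01 = c001 * (1 - fx) + c101 * fx;
    const double c11 = c011 * (1 - fx) + c111 * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
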