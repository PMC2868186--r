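#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 3D connected-component labelling on a logical voxel grid stored in
// R array order (z fastest: dims = (nz, ny, nx)). connectivity is 6, 18 or 26.
// Labels are assigned in scan order starting at 1; background stays 0.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets in (dz, dy, dx)
  std::vector<int> dz, dy, dx;
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        int m = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  const int nb = (int)dz.size();

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int cz = (int)(cur % nz);
      int cy = (int)((cur / nz) % ny);
      int cx = (int)(cur / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nb; ++k) {
        int z = cz + dz[k], y = cy + dy[k], x = cx + dx[k];
        if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
        R_xlen_t q = (R_xlen_t)x * nz * ny + (R_xlen_t)y * nz + z;
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = next;
  return lab;
}

// 1D squared distance transform (lower envelope of parabolas).
static void dt1d(const double *f, double *d, int n, int *v, double *z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance from every pixel to the nearest TRUE pixel
// of a 2D logical mask (column-major, dims = (ny, nx)). Pixels of an all-FALSE
// mask get +Inf. A large finite sentinel keeps the parabola envelope
// arithmetic well defined where no source pixel exists.
// [[Rcpp::export(name = ".edt_sq_2d")]]
NumericMatrix edt_sq_2d(LogicalMatrix mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  const double LARGE = 1e20;
  NumericMatrix d(ny, nx);
  const int nmax = std::max(ny, nx);
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int x = 0; x < nx; ++x) {          // along columns
    for (int y = 0; y < ny; ++y) f[y] = mask(y, x) ? 0.0 : LARGE;
    dt1d(f.data(), dd.data(), ny, v.data(), z.data());
    for (int y = 0; y < ny; ++y) d(y, x) = dd[y];
  }
  for (int y = 0; y < ny; ++y) {          // along rows
    for (int x = 0; x < nx; ++x) f[x] = d(y, x);
    dt1d(f.data(), dd.data(), nx, v.data(), z.data());
    for (int x = 0; x < nx; ++x)
      d(y, x) = dd[x] >= 1e18 ? std::numeric_limits<double>::infinity() : dd[x];
  }
  return d;
}
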