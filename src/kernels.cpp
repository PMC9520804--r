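// 3D voxel-grid kernels backing nucleus segmentation and telomere spot
// detection. Arrays are R arrays with dim = c(nz, ny, nx); the first index
// (z) varies fastest, matching the stack convention used on the R side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// Separable Gaussian blur; sigma in voxel units per axis (z, y, x).
// Kernel truncated at `truncate` sigmas and renormalised, so total flux is
// conserved away from the array edges.
// [[Rcpp::export(name = ".cpp_gaussian_blur3d")]]
NumericVector cpp_gaussian_blur3d(NumericVector arr, NumericVector sigma,
                                  double truncate = 4.0) {
  IntegerVector dim = arr.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n[3] = {nz, ny, nx};
  std::vector<double> a(arr.begin(), arr.end());
  std::vector<double> b(a.size());

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(truncate * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); ksum += k[i + r]; }
    for (double &v : k) v /= ksum;

    int len = n[ax];
    // stride of this axis in the flattened array
    R_xlen_t stride = 1;
    for (int j = 0; j < ax; ++j) stride *= n[j];
    R_xlen_t total = (R_xlen_t)nz * ny * nx;
    R_xlen_t nlines = total / len;
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // base index of this line: decompose line over the other two axes
      R_xlen_t lo = line % stride;                 // within-block offset
      R_xlen_t hi = line / stride;                 // block index beyond axis
      R_xlen_t base = lo + hi * stride * len;
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        int j0 = std::max(0, i - r), j1 = std::min(len - 1, i + r);
        for (int j = j0; j <= j1; ++j) acc += a[base + (R_xlen_t)j * stride] * k[j - i + r];
        b[base + (R_xlen_t)i * stride] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Negated 3D Laplacian with physical spacing (nm per voxel along z, y, x),
// normalised by the lateral spacing squared so values are spacing-relative.
// Positive peaks at bright blobs.
// [[Rcpp::export(name = ".cpp_neg_laplacian3d")]]
NumericVector cpp_neg_laplacian3d(NumericVector arr, NumericVector spacing_zyx) {
  IntegerVector dim = arr.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double hz = spacing_zyx[0], hy = spacing_zyx[1], hx = spacing_zyx[2];
  double norm = hx * hx; // reference scale
  double wz = norm / (hz * hz), wy = norm / (hy * hy), wx = 1.0;
  NumericVector out(arr.size());
  out.attr("dim") = dim;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        double c = arr[i], acc = 0;
        double zm = (z > 0) ? arr[idx3(z - 1, y, x, nz, ny)] : c;
        double zp = (z < nz - 1) ? arr[idx3(z + 1, y, x, nz, ny)] : c;
        double ym = (y > 0) ? arr[idx3(z, y - 1, x, nz, ny)] : c;
        double yp = (y < ny - 1) ? arr[idx3(z, y + 1, x, nz, ny)] : c;
        double xm = (x > 0) ? arr[idx3(z, y, x - 1, nz, ny)] : c;
        double xp = (x < nx - 1) ? arr[idx3(z, y, x + 1, nz, ny)] : c;
        acc += wz * (2 * c - zm - zp);
        acc += wy * (2 * c - ym - yp);
        acc += wx * (2 * c - xm - xp);
        out[i] = acc;
      }
  return out;
}

// Local maxima over the 26-neighbourhood, restricted to mask voxels, with
// response strictly above `threshold`. Plateau ties are broken by the lowest
// linear index: a voxel loses if any neighbour has a larger value, or an
// equal value at a smaller index. Returns 1-based linear indices.
// [[Rcpp::export(name = ".cpp_local_maxima3d")]]
IntegerVector cpp_local_maxima3d(NumericVector arr, LogicalVector mask,
                                 double threshold) {
  IntegerVector dim = arr.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> hits;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i]) continue;
        double v = arr[i];
        if (!(v > threshold)) continue;
        bool is_max = true;
        for (int dx = -1; dx <= 1 && is_max; ++dx)
          for (int dy = -1; dy <= 1 && is_max; ++dy)
            for (int dz = -1; dz <= 1 && is_max; ++dz) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
              R_xlen_t j = idx3(Z, Y, X, nz, ny);
              double w = arr[j];
              if (w > v || (w == v && j < i)) is_max = false;
            }
        if (is_max) hits.push_back((int)(i + 1));
      }
  return IntegerVector(hits.begin(), hits.end());
}

// 6-connected component labelling of a binary mask. Returns integer labels
// (0 = background), numbered in scan order.
// [[Rcpp::export(name = ".cpp_label_components3d")]]
IntegerVector cpp_label_components3d(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t total = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(total, 0);
  lab.attr("dim") = dim;
  int next = 0;
  std::vector<R_xlen_t> stack;
  const int dzs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dxs[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t i = 0; i < total; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (int d = 0; d < 6; ++d) {
        int Z = z + dzs[d], Y = y + dys[d], X = x + dxs[d];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        R_xlen_t j = idx3(Z, Y, X, nz, ny);
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

static LogicalVector morph3d(LogicalVector mask, IntegerVector radius, bool dilate) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int rz = radius[0], ry = radius[1], rx = radius[2];
  // ellipsoidal structuring element offsets
  std::vector<int> oz, oy, ox;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        double q = 0;
        if (rz > 0) q += (double)dz * dz / (rz * rz);
        if (ry > 0) q += (double)dy * dy / (ry * ry);
        if (rx > 0) q += (double)dx * dx / (rx * rx);
        if (q <= 1.0 + 1e-9) { oz.push_back(dz); oy.push_back(dy); ox.push_back(dx); }
      }
  R_xlen_t total = (R_xlen_t)nz * ny * nx;
  LogicalVector out(total, dilate ? FALSE : TRUE);
  out.attr("dim") = dim;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        bool hit = dilate ? false : true;
        for (size_t k = 0; k < oz.size(); ++k) {
          int Z = z + oz[k], Y = y + oy[k], X = x + ox[k];
          bool v;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
            v = false; // outside treated as background
          else
            v = mask[idx3(Z, Y, X, nz, ny)];
          if (dilate) { if (v) { hit = true; break; } }
          else       { if (!v) { hit = false; break; } }
        }
        out[i] = hit;
      }
  return out;
}

// Binary closing (dilation then erosion) with an ellipsoidal structuring
// element of voxel radii (z, y, x).
// [[Rcpp::export(name = ".cpp_binary_closing3d")]]
LogicalVector cpp_binary_closing3d(LogicalVector mask, IntegerVector radius) {
  return morph3d(morph3d(mask, radius, true), radius, false);
}
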