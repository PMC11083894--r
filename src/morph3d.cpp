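#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Arrays are indexed (z, y, x): dim = c(nz, ny, nx), z fastest (column-major).
// Edge handling for rank filters and morphology is mirror reflection, so a
// constant image stays constant under every filter.

static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector median3d_cpp(NumericVector img, int rz, int ry, int rx) {
  IntegerVector d = img.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  NumericVector out(img.size());
  out.attr("dim") = d;
  std::vector<double> buf((2 * rz + 1) * (2 * ry + 1) * (2 * rx + 1));
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t m = 0;
        for (int dx = -rx; dx <= rx; ++dx) {
          int xx = reflect(x + dx, nx);
          for (int dy = -ry; dy <= ry; ++dy) {
            int yy = reflect(y + dy, ny);
            for (int dz = -rz; dz <= rz; ++dz) {
              int zz = reflect(z + dz, nz);
              buf[m++] = img[zz + (size_t)nz * (yy + (size_t)ny * xx)];
            }
          }
        }
        size_t half = m / 2;
        std::nth_element(buf.begin(), buf.begin() + half, buf.begin() + m);
        double med = buf[half];
        if (m % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + half);
          med = 0.5 * (med + lo);
        }
        out[z + (size_t)nz * (y + (size_t)ny * x)] = med;
      }
  return out;
}

// Grayscale erosion (op = 0) or dilation (op = 1) with an arbitrary flat
// structuring element given as an m x 3 matrix of (dz, dy, dx) offsets.
// [[Rcpp::export]]
NumericVector morph3d_cpp(NumericVector img, IntegerMatrix se, int op) {
  IntegerVector d = img.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  int m = se.nrow();
  NumericVector out(img.size());
  out.attr("dim") = d;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double acc = (op == 0) ? R_PosInf : R_NegInf;
        for (int k = 0; k < m; ++k) {
          int zz = reflect(z + se(k, 0), nz);
          int yy = reflect(y + se(k, 1), ny);
          int xx = reflect(x + se(k, 2), nx);
          double v = img[zz + (size_t)nz * (yy + (size_t)ny * xx)];
          if (op == 0) { if (v < acc) acc = v; } else { if (v > acc) acc = v; }
        }
        out[z + (size_t)nz * (y + (size_t)ny * x)] = acc;
      }
  return out;
}

// Connected-component labelling of a logical mask under 6/18/26 connectivity.
// Labels are assigned in first-encounter order of a (z, y, x) lexicographic
// scan (z outermost), so the labelling is deterministic.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = d;

  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ord = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        nb.push_back({dz, dy, dx});
      }

  int next = 0;
  std::vector<size_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = z + (size_t)nz * (y + (size_t)ny * x);
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          size_t cur = stack.back();
          stack.pop_back();
          int cz = cur % nz;
          size_t rest = cur / nz;
          int cy = rest % ny;
          int cx = rest / ny;
          for (auto &o : nb) {
            int zz = cz + o[0], yy = cy + o[1], xx = cx + o[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            size_t j = zz + (size_t)nz * (yy + (size_t)ny * xx);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  return lab;
}

// Fill internal cavities: background voxels not 6-connected to the array
// border become foreground; foreground is never removed.
// [[Rcpp::export]]
LogicalVector fillholes3d_cpp(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  size_t n = mask.size();
  std::vector<char> outside(n, 0);
  std::vector<size_t> stack;

  auto push = [&](int z, int y, int x) {
    size_t i = z + (size_t)nz * (y + (size_t)ny * x);
    if (!mask[i] && !outside[i]) {
      outside[i] = 1;
      stack.push_back(i);
    }
  };
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      push(0, y, x);
      push(nz - 1, y, x);
    }
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      push(z, 0, x);
      push(z, ny - 1, x);
    }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      push(z, y, 0);
      push(z, y, nx - 1);
    }
  const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  while (!stack.empty()) {
    size_t cur = stack.back();
    stack.pop_back();
    int cz = cur % nz;
    size_t rest = cur / nz;
    int cy = rest % ny;
    int cx = rest / ny;
    for (int k = 0; k < 6; ++k) {
      int zz = cz + off[k][0], yy = cy + off[k][1], xx = cx + off[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      size_t j = zz + (size_t)nz * (yy + (size_t)ny * xx);
      if (!mask[j] && !outside[j]) {
        outside[j] = 1;
        stack.push_back(j);
      }
    }
  }
  LogicalVector out(n);
  out.attr("dim") = d;
  for (size_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

static void blur_axis(std::vector<double> &v, std::vector<double> &tmp,
                      int nz, int ny, int nx, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &w : k) w /= s;
  int n[3] = {nz, ny, nx};
  size_t stride[3] = {1, (size_t)nz, (size_t)nz * ny};
  int na = n[axis];
  size_t sa = stride[axis];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int idx3[3] = {z, y, x};
        if (idx3[axis] != 0) continue;  // walk each line once
        size_t base = z + (size_t)nz * (y + (size_t)ny * x);
        for (int i = 0; i < na; ++i) {
          double acc = 0;
          for (int j = -r; j <= r; ++j)
            acc += k[j + r] * v[base + sa * reflect(i + j, na)];
          tmp[base + sa * i] = acc;
        }
      }
  std::swap(v, tmp);
}

// Separable Gaussian blur with per-axis sigmas in voxel units.
// [[Rcpp::export]]
NumericVector blur3d_cpp(NumericVector img, double sz, double sy, double sx) {
  IntegerVector d = img.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  std::vector<double> v(img.begin(), img.end()), tmp(v.size());
  blur_axis(v, tmp, nz, ny, nx, 0, sz);
  blur_axis(v, tmp, nz, ny, nx, 1, sy);
  blur_axis(v, tmp, nz, ny, nx, 2, sx);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = d;
  return out;
}
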