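#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim = c(nz, ny, nx), column-major:
// linear index = z + nz * (y + ny * x), all 0-based here.

// 1-D convolution along one axis (0 = z, 1 = y, 2 = x) with replicate
// (clamped) boundary handling. Kernel length must be odd.
// [[Rcpp::export]]
NumericVector conv3d_axis(const NumericVector& vol, const IntegerVector& dim,
                          const NumericVector& kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const int k = kernel.size();
  const int half = k / 2;
  const int len = dim[axis];
  NumericVector out(n);
  const R_xlen_t strides[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  const R_xlen_t stride = strides[axis];

  // iterate over every line along `axis`
  int odim[2]; R_xlen_t ostr[2]; int m = 0;
  for (int a = 0; a < 3; ++a) if (a != axis) { odim[m] = dim[a]; ostr[m] = strides[a]; ++m; }

  for (int i = 0; i < odim[0]; ++i) {
    for (int j = 0; j < odim[1]; ++j) {
      const R_xlen_t base = i * ostr[0] + j * ostr[1];
      for (int p = 0; p < len; ++p) {
        double acc = 0.0;
        for (int q = 0; q < k; ++q) {
          int idx = p + q - half;
          if (idx < 0) idx = 0; else if (idx >= len) idx = len - 1;
          acc += kernel[q] * vol[base + (R_xlen_t)idx * stride];
        }
        out[base + (R_xlen_t)p * stride] = acc;
      }
    }
  }
  return out;
}

// 3-D median filter with a size^3 window (size odd), replicate boundaries.
// [[Rcpp::export]]
NumericVector median3d(const NumericVector& vol, const IntegerVector& dim, int size) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int half = size / 2;
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve((size_t)size * size * size);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        for (int dx = -half; dx <= half; ++dx) {
          int xx = std::min(std::max(x + dx, 0), nx - 1);
          for (int dy = -half; dy <= half; ++dy) {
            int yy = std::min(std::max(y + dy, 0), ny - 1);
            for (int dz = -half; dz <= half; ++dz) {
              int zz = std::min(std::max(z + dz, 0), nz - 1);
              buf.push_back(vol[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)]);
            }
          }
        }
        size_t mid = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = buf[mid];
      }
    }
  }
  return out;
}

// Local maxima over the 26-neighbourhood (>= all neighbours, > min_value).
// Returns 0-based linear indices.
// [[Rcpp::export]]
IntegerVector local_maxima3d(const NumericVector& vol, const IntegerVector& dim,
                             double min_value) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> hits;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        const double v = vol[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
        if (!(v > min_value)) continue;
        bool is_max = true;
        for (int dx = -1; dx <= 1 && is_max; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1 && is_max; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              int zz = z + dz; if (zz < 0 || zz >= nz) continue;
              if (dx == 0 && dy == 0 && dz == 0) continue;
              if (vol[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] > v) { is_max = false; break; }
            }
          }
        }
        if (is_max) hits.push_back((int)(z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)));
      }
    }
  }
  return wrap(hits);
}

// Nearest-centre (Voronoi) labels under Euclidean distance in physical
// units. centres: m x 3 matrix of 0-based voxel coordinates (z, y, x).
// Ties broken by the lowest centre index (strict < update, ascending scan).
// Returns 1-based labels.
// [[Rcpp::export]]
IntegerVector nearest_centre_labels(const IntegerVector& dim, const NumericMatrix& centres,
                                    const NumericVector& voxel_size) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int m = centres.nrow();
  const double sz = voxel_size[0], sy = voxel_size[1], sx = voxel_size[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  std::vector<double> best(n, R_PosInf);
  for (int c = 0; c < m; ++c) {
    const double cz = centres(c, 0), cy = centres(c, 1), cx = centres(c, 2);
    for (int x = 0; x < nx; ++x) {
      const double ddx = (x - cx) * sx; const double dx2 = ddx * ddx;
      for (int y = 0; y < ny; ++y) {
        const double ddy = (y - cy) * sy; const double dxy2 = dx2 + ddy * ddy;
        R_xlen_t idx = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        for (int z = 0; z < nz; ++z, ++idx) {
          const double ddz = (z - cz) * sz;
          const double d2 = dxy2 + ddz * ddz;
          if (d2 < best[idx]) { best[idx] = d2; lab[idx] = c + 1; }
        }
      }
    }
  }
  return lab;
}

// 6-connected components of a logical mask. Returns integer labels
// (0 = background), components numbered in scan order.
// [[Rcpp::export]]
IntegerVector label_components3d(const LogicalVector& mask, const IntegerVector& dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
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
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % nz);
      int rest = (int)(cur / nz);
      int y = rest % ny;
      int x = rest / ny;
      const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t ni = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[ni] && lab[ni] == 0) { lab[ni] = next; stack.push_back(ni); }
      }
    }
  }
  return lab;
}
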