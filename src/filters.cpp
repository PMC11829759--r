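#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Arrays are R 3D arrays with dim (nz, ny, nx), column-major:
// linear index = z + nz * (y + ny * x).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Exact sliding-window adaptive histogram equalisation: each voxel is mapped
// to its mid-rank within the local window (border windows are clipped to the
// volume). Window extents below/above the centre are passed separately so
// even window sizes are representable. Output lies in [0, 1] by construction.
// [[Rcpp::export(name = ".cpp_ahe3d")]]
NumericVector cpp_ahe3d(NumericVector img, IntegerVector dim,
                        IntegerVector win_lo, IntegerVector win_hi) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(img.size());
  for (int x = 0; x < nx; ++x) {
    const int x0 = clampi(x - win_lo[2], 0, nx - 1), x1 = clampi(x + win_hi[2], 0, nx - 1);
    for (int y = 0; y < ny; ++y) {
      const int y0 = clampi(y - win_lo[1], 0, ny - 1), y1 = clampi(y + win_hi[1], 0, ny - 1);
      for (int z = 0; z < nz; ++z) {
        const int z0 = clampi(z - win_lo[0], 0, nz - 1), z1 = clampi(z + win_hi[0], 0, nz - 1);
        const double v = img[z + nz * (y + ny * x)];
        long below = 0, equal = 0, n = 0;
        for (int xx = x0; xx <= x1; ++xx) {
          for (int yy = y0; yy <= y1; ++yy) {
            const R_xlen_t base = nz * (yy + (R_xlen_t)ny * xx);
            for (int zz = z0; zz <= z1; ++zz) {
              const double w = img[zz + base];
              if (w < v) ++below; else if (w == v) ++equal;
              ++n;
            }
          }
        }
        // mid-rank CDF estimate; constant windows map to 0.5
        out[z + nz * (y + ny * x)] = (below + 0.5 * equal) / (double)n;
      }
    }
  }
  return out;
}

// Separable 1D convolution along a chosen axis (0 = z, 1 = y, 2 = x) with
// reflective (mirror) boundary handling. Kernel length must be odd.
// [[Rcpp::export(name = ".cpp_conv1d_axis")]]
NumericVector cpp_conv1d_axis(NumericVector img, IntegerVector dim,
                              NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int klen = kernel.size();
  const int kh = klen / 2;
  NumericVector out(img.size());
  const int n_axis = (axis == 0) ? nz : (axis == 1 ? ny : nx);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        const int pos = (axis == 0) ? z : (axis == 1 ? y : x);
        double acc = 0.0;
        for (int k = -kh; k <= kh; ++k) {
          int p = pos + k;
          // mirror without repeating the edge sample (scipy 'mirror' style)
          if (n_axis > 1) {
            while (p < 0 || p >= n_axis) {
              if (p < 0) p = -p;
              if (p >= n_axis) p = 2 * (n_axis - 1) - p;
            }
          } else {
            p = 0;
          }
          int zz = z, yy = y, xx = x;
          if (axis == 0) zz = p; else if (axis == 1) yy = p; else xx = p;
          acc += kernel[k + kh] * img[zz + nz * (yy + (R_xlen_t)ny * xx)];
        }
        out[z + nz * (y + ny * x)] = acc;
      }
    }
  }
  return out;
}

// 3D median filter with an odd box window; borders clip the window.
// [[Rcpp::export(name = ".cpp_median3d")]]
NumericVector cpp_median3d(NumericVector img, IntegerVector dim, IntegerVector halfwin) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int hz = halfwin[0], hy = halfwin[1], hx = halfwin[2];
  NumericVector out(img.size());
  std::vector<double> buf;
  buf.reserve((2 * hz + 1) * (2 * hy + 1) * (2 * hx + 1));
  for (int x = 0; x < nx; ++x) {
    const int x0 = clampi(x - hx, 0, nx - 1), x1 = clampi(x + hx, 0, nx - 1);
    for (int y = 0; y < ny; ++y) {
      const int y0 = clampi(y - hy, 0, ny - 1), y1 = clampi(y + hy, 0, ny - 1);
      for (int z = 0; z < nz; ++z) {
        const int z0 = clampi(z - hz, 0, nz - 1), z1 = clampi(z + hz, 0, nz - 1);
        buf.clear();
        for (int xx = x0; xx <= x1; ++xx)
          for (int yy = y0; yy <= y1; ++yy) {
            const R_xlen_t base = nz * (yy + (R_xlen_t)ny * xx);
            for (int zz = z0; zz <= z1; ++zz) buf.push_back(img[zz + base]);
          }
        const size_t n = buf.size();
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
        double med = buf[n / 2];
        if (n % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + n / 2 - 1, buf.begin() + n / 2);
          med = 0.5 * (med + buf[n / 2 - 1]);
        }
        out[z + nz * (y + ny * x)] = med;
      }
    }
  }
  return out;
}

// Pairwise footprint overlaps between two 2D label images on the same grid.
// Returns a 3-column matrix (label_a, label_b, n_pixels) for co-occurring
// positive labels.
// [[Rcpp::export(name = ".cpp_label_overlaps")]]
IntegerMatrix cpp_label_overlaps(IntegerVector a, IntegerVector b) {
  std::map<std::pair<int, int>, int> counts;
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] > 0 && b[i] > 0) counts[std::make_pair(a[i], b[i])]++;
  }
  IntegerMatrix out(counts.size(), 3);
  int r = 0;
  for (auto &kv : counts) {
    out(r, 0) = kv.first.first;
    out(r, 1) = kv.first.second;
    out(r, 2) = kv.second;
    ++r;
  }
  return out;
}
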