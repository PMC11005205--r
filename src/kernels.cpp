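#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 6-connected component labelling of a 3-D logical array.
// Components are numbered in order of first (smallest) linear index, so the
// label ids themselves encode the deterministic tie-break rule used by
// largest_component().
// [[Rcpp::export(name = ".cc_label6")]]
IntegerVector cc_label6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

static inline double get3(const NumericVector &v, int nx, int ny,
                          int x, int y, int z) {
  return v[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
}

// Trilinear sampling of a 3-D volume at continuous 0-based voxel coordinates.
// Points outside the grid return `background`.
// [[Rcpp::export(name = ".sample_trilinear")]]
NumericVector sample_trilinear(NumericVector src, IntegerVector dim,
                               NumericVector px, NumericVector py,
                               NumericVector pz, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = px.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = px[i], y = py[i], z = pz[i];
    if (!(x > -1.0 && x < nx && y > -1.0 && y < ny && z > -1.0 && z < nz)) {
      out[i] = background; continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0, wsum = 0.0;
    for (int c = 0; c < 8; ++c) {
      int xi = x0 + (c & 1), yi = y0 + ((c >> 1) & 1), zi = z0 + ((c >> 2) & 1);
      double w = ((c & 1) ? fx : 1 - fx) * (((c >> 1) & 1) ? fy : 1 - fy) *
                 (((c >> 2) & 1) ? fz : 1 - fz);
      if (w <= 0) continue;
      if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz) {
        acc += w * background;
      } else {
        acc += w * get3(src, nx, ny, xi, yi, zi);
      }
      wsum += w;
    }
    out[i] = (wsum > 0) ? acc / wsum : background;
  }
  return out;
}

// Nearest-neighbour sampling; never invents values, so suitable for labels.
// [[Rcpp::export(name = ".sample_nearest")]]
NumericVector sample_nearest(NumericVector src, IntegerVector dim,
                             NumericVector px, NumericVector py,
                             NumericVector pz, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = px.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int x = (int)std::lround(px[i]);
    int y = (int)std::lround(py[i]);
    int z = (int)std::lround(pz[i]);
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) {
      out[i] = background;
    } else {
      out[i] = get3(src, nx, ny, x, y, z);
    }
  }
  return out;
}

// Separable 1-D convolution along one axis (1 = x, 2 = y, 3 = z) with
// replicate-edge padding. Kernel length must be odd.
// [[Rcpp::export(name = ".conv_axis")]]
NumericVector conv_axis(NumericVector vol, IntegerVector dim,
                        NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size(), kh = kl / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0;
        for (int k = 0; k < kl; ++k) {
          int o = k - kh;
          int xi = x, yi = y, zi = z;
          if (axis == 1) xi = std::min(std::max(x + o, 0), nx - 1);
          else if (axis == 2) yi = std::min(std::max(y + o, 0), ny - 1);
          else zi = std::min(std::max(z + o, 0), nz - 1);
          acc += kernel[k] * get3(vol, nx, ny, xi, yi, zi);
        }
        out[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = acc;
      }
    }
  }
  return out;
}
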