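#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 3D connected-component labelling on a logical mask (column-major array).
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity = 6) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);

  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int noff = (int)dx.size();

  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++current;
    labels[s] = current;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int k = 0; k < noff; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

// In-plane (per axial slice) binary dilation or erosion with a disc of the
// given radius in voxels. op: 1 = dilate, 0 = erode.
// [[Rcpp::export(name = ".morph_inplane")]]
LogicalVector morph_inplane(LogicalVector mask, IntegerVector dims, int radius, int op) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);

  std::vector<int> ox, oy;
  for (int cy = -radius; cy <= radius; ++cy)
    for (int cx = -radius; cx <= radius; ++cx)
      if (cx * cx + cy * cy <= radius * radius) { ox.push_back(cx); oy.push_back(cy); }
  const int noff = (int)ox.size();

  for (int z = 0; z < nz; ++z) {
    R_xlen_t base = (R_xlen_t)z * nx * ny;
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        bool hit = (op == 1) ? false : true;
        for (int k = 0; k < noff; ++k) {
          int xx = x + ox[k], yy = y + oy[k];
          bool v;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny)
            v = false;  // outside the grid counts as background
          else
            v = mask[base + (R_xlen_t)yy * nx + xx];
          if (op == 1) { if (v) { hit = true; break; } }
          else         { if (!v) { hit = false; break; } }
        }
        out[base + (R_xlen_t)y * nx + x] = hit;
      }
    }
  }
  return out;
}

// Per-voxel local reference intensity over a mask: for every masked voxel the
// median (or mean) of masked intensities inside the in-plane square window of
// the given radius, excluding the centre voxel itself. Also returns the
// number of contributing neighbours. Unmasked voxels get NA / 0.
// [[Rcpp::export(name = ".local_masked_reference")]]
List local_masked_reference(NumericVector img, LogicalVector mask, IntegerVector dims,
                            int radius, bool use_median) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector ref(n, NA_REAL);
  IntegerVector cnt(n, 0);
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1));

  for (int z = 0; z < nz; ++z) {
    R_xlen_t base = (R_xlen_t)z * nx * ny;
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = base + (R_xlen_t)y * nx + x;
        if (!mask[v]) continue;
        buf.clear();
        int y0 = std::max(0, y - radius), y1 = std::min(ny - 1, y + radius);
        int x0 = std::max(0, x - radius), x1 = std::min(nx - 1, x + radius);
        for (int yy = y0; yy <= y1; ++yy)
          for (int xx = x0; xx <= x1; ++xx) {
            if (xx == x && yy == y) continue;
            R_xlen_t w = base + (R_xlen_t)yy * nx + xx;
            if (mask[w]) buf.push_back(img[w]);
          }
        cnt[v] = (int)buf.size();
        if (buf.empty()) continue;
        if (use_median) {
          size_t mid = buf.size() / 2;
          std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
          double m = buf[mid];
          if (buf.size() % 2 == 0) {
            double lo = *std::max_element(buf.begin(), buf.begin() + mid);
            m = 0.5 * (m + lo);
          }
          ref[v] = m;
        } else {
          double s = 0.0;
          for (double t : buf) s += t;
          ref[v] = s / buf.size();
        }
      }
    }
  }
  return List::create(_["reference"] = ref, _["n_neighbors"] = cnt);
}
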