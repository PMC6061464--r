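#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Flood fills on 3D logical grids.  dims = (nx, ny, nz), column-major
// (x fastest), matching R array layout.

// [[Rcpp::export(name = ".flood_fill_26")]]
LogicalVector flood_fill_26(LogicalVector fg, IntegerVector dims,
                            IntegerVector seed) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long nxy = (long)nx * ny;
  long s = (seed[0] - 1) + (long)(seed[1] - 1) * nx +
           (long)(seed[2] - 1) * nxy;
  LogicalVector out(fg.size(), false);
  if (!fg[s]) return out;
  std::vector<long> stack;
  stack.push_back(s);
  out[s] = true;
  while (!stack.empty()) {
    long cur = stack.back();
    stack.pop_back();
    int i = (int)(cur % nx);
    int j = (int)((cur / nx) % ny);
    int k = (int)(cur / nxy);
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          long q = ii + (long)jj * nx + (long)kk * nxy;
          if (fg[q] && !out[q]) {
            out[q] = true;
            stack.push_back(q);
          }
        }
      }
    }
  }
  return out;
}

// Background voxels 6-connected to any exterior face of the grid.
// Holes are background voxels NOT marked by this fill.
// [[Rcpp::export(name = ".exterior_background_6")]]
LogicalVector exterior_background_6(LogicalVector fg, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long nxy = (long)nx * ny, ntot = nxy * nz;
  LogicalVector out(fg.size(), false);
  std::vector<long> stack;
  for (long q = 0; q < ntot; ++q) {
    int i = (int)(q % nx);
    int j = (int)((q / nx) % ny);
    int k = (int)(q / nxy);
    bool face = (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 || k == 0 ||
                 k == nz - 1);
    if (face && !fg[q] && !out[q]) {
      out[q] = true;
      stack.push_back(q);
    }
  }
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    long cur = stack.back();
    stack.pop_back();
    int i = (int)(cur % nx);
    int j = (int)((cur / nx) % ny);
    int k = (int)(cur / nxy);
    for (int d = 0; d < 6; ++d) {
      int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      long q = ii + (long)jj * nx + (long)kk * nxy;
      if (!fg[q] && !out[q]) {
        out[q] = true;
        stack.push_back(q);
      }
    }
  }
  return out;
}
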