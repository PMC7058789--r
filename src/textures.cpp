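#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Quantized ROIs are passed as integer 3D arrays with 0 marking voxels
// outside the ROI and levels 1..ng inside. All four matrix builders share
// the 13 unique 3D direction offsets (one representative per +/- pair).

static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Symmetric co-occurrence counts at the given distance, summed over the
// 13 directions (both orderings of each pair are counted).
// [[Rcpp::export(name = ".glcm_counts")]]
NumericMatrix glcm_counts(IntegerVector lev, IntegerVector dims, int ng,
                          int distance, IntegerVector dirsel) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix m(ng, ng);
  for (int di = 0; di < dirsel.size(); ++di) {
    int d = dirsel[di] - 1;
    int dx = DIRS[d][0] * distance, dy = DIRS[d][1] * distance,
        dz = DIRS[d][2] * distance;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = lev[idx3(x, y, z, nx, ny)];
          if (i == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int j = lev[idx3(x2, y2, z2, nx, ny)];
          if (j == 0) continue;
          m(i - 1, j - 1) += 1.0;
          m(j - 1, i - 1) += 1.0;
        }
  }
  return m;
}

// Run-length counts: maximal runs of equal level along each direction,
// truncated wherever the line leaves the ROI, summed over directions.
// [[Rcpp::export(name = ".glrlm_counts")]]
NumericMatrix glrlm_counts(IntegerVector lev, IntegerVector dims, int ng,
                           IntegerVector dirsel) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlen = nx + ny + nz;  // safe upper bound on run length
  NumericMatrix m(ng, maxlen);
  for (int di = 0; di < dirsel.size(); ++di) {
    int d = dirsel[di] - 1;
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          // start of a grid line in this direction?
          int px = x - dx, py = y - dy, pz = z - dz;
          bool is_start = (px < 0 || px >= nx || py < 0 || py >= ny ||
                           pz < 0 || pz >= nz);
          if (!is_start) continue;
          int cur = 0, len = 0;
          int cx = x, cy = y, cz = z;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 &&
                 cz < nz) {
            int v = lev[idx3(cx, cy, cz, nx, ny)];
            if (v == cur) {
              ++len;
            } else {
              if (cur > 0) m(cur - 1, len - 1) += 1.0;
              cur = v;
              len = 1;
            }
            cx += dx; cy += dy; cz += dz;
          }
          if (cur > 0) m(cur - 1, len - 1) += 1.0;
        }
  }
  return m;
}

// Zones: 26-connected components of equal-level ROI voxels. Returns a
// two-column matrix (level, size), one row per zone.
// [[Rcpp::export(name = ".glszm_zones")]]
IntegerMatrix glszm_zones(IntegerVector lev, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zlev, zsize, stack;
  for (int s = 0; s < n; ++s) {
    if (lev[s] == 0 || seen[s]) continue;
    int level = lev[s], size = 0;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      ++size;
      int cz = c / (nx * ny), rem = c % (nx * ny);
      int cy = rem / nx, cx = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                z2 >= nz)
              continue;
            int t = idx3(x2, y2, z2, nx, ny);
            if (!seen[t] && lev[t] == level) {
              seen[t] = 1;
              stack.push_back(t);
            }
          }
    }
    zlev.push_back(level);
    zsize.push_back(size);
  }
  IntegerMatrix out(zlev.size(), 2);
  for (size_t i = 0; i < zlev.size(); ++i) {
    out(i, 0) = zlev[i];
    out(i, 1) = zsize[i];
  }
  return out;
}

// Neighbourhood gray-tone difference: for each level i, s(i) = sum over ROI
// voxels at level i of |i - mean level of its 26-neighbourhood inside the
// ROI| (voxels with no ROI neighbour contribute 0), and n(i) = voxel count.
// [[Rcpp::export(name = ".ngtdm_stats")]]
NumericMatrix ngtdm_stats(IntegerVector lev, IntegerVector dims, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 2);  // columns: s(i), n(i)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lev[idx3(x, y, z, nx, ny)];
        if (i == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              int j = lev[idx3(x2, y2, z2, nx, ny)];
              if (j > 0) {
                sum += j;
                ++cnt;
              }
            }
        if (cnt > 0) out(i - 1, 0) += std::abs(i - sum / cnt);
        out(i - 1, 1) += 1.0;
      }
  return out;
}
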