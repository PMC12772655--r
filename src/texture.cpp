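// Gray-level texture matrix construction on 3D discretized grids.
// Grids are column-major integer arrays: level 0 = outside mask,
// levels 1..ng inside the mask.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline bool in_grid(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// Gray-level co-occurrence counts, one ng x ng slab per offset
// (not symmetrized; callers symmetrize with P + t(P)).
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector lev, IntegerVector dim,
                       IntegerMatrix offsets, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int K = offsets.nrow();
  NumericVector counts((R_xlen_t)ng * ng * K);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        int li = lev[idx];
        if (li == 0) continue;
        for (int k = 0; k < K; ++k) {
          int x2 = x + offsets(k, 0), y2 = y + offsets(k, 1),
              z2 = z + offsets(k, 2);
          if (!in_grid(x2, y2, z2, nx, ny, nz)) continue;
          int lj = lev[x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2)];
          if (lj == 0) continue;
          counts[(li - 1) + (R_xlen_t)ng * (lj - 1) + (R_xlen_t)ng * ng * k] += 1.0;
        }
      }
  counts.attr("dim") = IntegerVector::create(ng, ng, K);
  return counts;
}

// Run-length counts, one ng x maxrun slab per offset direction.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector lev, IntegerVector dim,
                        IntegerMatrix offsets, int ng, int maxrun) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int K = offsets.nrow();
  NumericVector counts((R_xlen_t)ng * maxrun * K);
  for (int k = 0; k < K; ++k) {
    int ox = offsets(k, 0), oy = offsets(k, 1), oz = offsets(k, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          int li = lev[idx];
          if (li == 0) continue;
          // run start: predecessor along -offset absent or different level
          int xp = x - ox, yp = y - oy, zp = z - oz;
          if (in_grid(xp, yp, zp, nx, ny, nz) &&
              lev[xp + (R_xlen_t)nx * (yp + (R_xlen_t)ny * zp)] == li)
            continue;
          int len = 1;
          int xn = x + ox, yn = y + oy, zn = z + oz;
          while (in_grid(xn, yn, zn, nx, ny, nz) &&
                 lev[xn + (R_xlen_t)nx * (yn + (R_xlen_t)ny * zn)] == li) {
            ++len;
            xn += ox; yn += oy; zn += oz;
          }
          if (len > maxrun) len = maxrun;
          counts[(li - 1) + (R_xlen_t)ng * (len - 1) +
                 (R_xlen_t)ng * maxrun * k] += 1.0;
        }
  }
  counts.attr("dim") = IntegerVector::create(ng, maxrun, K);
  return counts;
}

// Size-zone decomposition: 26-connected components of equal gray level.
// Returns the level and voxel count of every zone.
// [[Rcpp::export]]
List cpp_glszm_zones(IntegerVector lev, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> visited(n, 0);
  std::vector<int> zlev, zsize;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (visited[start] || lev[start] == 0) continue;
    int li = lev[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    visited[start] = 1;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      ++size;
      int cx = (int)(cur % nx), cy = (int)((cur / nx) % ny),
          cz = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (!in_grid(x2, y2, z2, nx, ny, nz)) continue;
            R_xlen_t idx = x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2);
            if (!visited[idx] && lev[idx] == li) {
              visited[idx] = 1;
              stack.push_back(idx);
            }
          }
    }
    zlev.push_back(li);
    zsize.push_back(size);
  }
  return List::create(_["level"] = wrap(zlev), _["size"] = wrap(zsize));
}

// Dependence counts: for each in-mask voxel, k = 1 + number of 26-neighbours
// (in mask) whose level differs by at most alpha.  Returns ng x 27 counts.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lev, IntegerVector dim, double alpha) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int ng = 0;
  for (R_xlen_t i = 0; i < lev.size(); ++i)
    if (lev[i] > ng) ng = lev[i];
  if (ng == 0) ng = 1;
  NumericMatrix counts(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        int li = lev[idx];
        if (li == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (!in_grid(x2, y2, z2, nx, ny, nz)) continue;
              int lj = lev[x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2)];
              if (lj == 0) continue;
              if (std::abs((double)(li - lj)) <= alpha) ++dep;
            }
        counts(li - 1, dep) += 1.0; // column index = dep, dependence k = dep+1
      }
  return counts;
}

// Neighbourhood gray-tone difference accumulators: per level, the number of
// contributing voxels and the summed |level - neighbourhood mean|.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lev, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix acc(ng, 2); // col 0: n_i, col 1: s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        int li = lev[idx];
        if (li == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (!in_grid(x2, y2, z2, nx, ny, nz)) continue;
              int lj = lev[x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2)];
              if (lj == 0) continue;
              sum += lj;
              ++cnt;
            }
        if (cnt == 0) continue;
        acc(li - 1, 0) += 1.0;
        acc(li - 1, 1) += std::fabs((double)li - sum / cnt);
      }
  return acc;
}

// Largest pairwise Euclidean distance among points (rows of an n x d matrix).
// [[Rcpp::export]]
double cpp_max_pairdist(NumericMatrix pts) {
  const int n = pts.nrow(), d = pts.ncol();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = pts(i, c) - pts(j, c);
        s += diff * diff;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}
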