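#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gray-level texture matrices over a 3D discretised ROI.  The level array
// `lv` holds consecutive integer gray levels 1..nlev inside the ROI and 0
// outside; `dims` is the 3D grid shape.

static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

inline int at(const IntegerVector& lv, int x, int y, int z,
              int nx, int ny, int nz) {
  if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
  return lv[x + nx * (y + ny * z)];
}

// Symmetric co-occurrence matrices, one per direction (unit distance).
// Returns nlev x nlev x 13 array of counts.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector lv, IntegerVector dims, int nlev) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(nlev * nlev * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double* M = &out[d * nlev * nlev];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int a = lv[x + nx * (y + ny * z)];
          if (!a) continue;
          const int b = at(lv, x + dx, y + dy, z + dz, nx, ny, nz);
          if (!b) continue;
          M[(a - 1) + nlev * (b - 1)] += 1.0;   // symmetric:
          M[(b - 1) + nlev * (a - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(nlev, nlev, 13);
  return out;
}

// Run-length matrices, one per direction: counts of maximal same-level runs
// by (level, run length).  Returns nlev x maxlen x 13.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector lv, IntegerVector dims, int nlev) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out(nlev * maxlen * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double* M = &out[d * nlev * maxlen];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int a = lv[x + nx * (y + ny * z)];
          if (!a) continue;
          // run starts here iff predecessor differs
          if (at(lv, x - dx, y - dy, z - dz, nx, ny, nz) == a) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (at(lv, cx, cy, cz, nx, ny, nz) == a) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          if (len > maxlen) len = maxlen;
          M[(a - 1) + nlev * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(nlev, maxlen, 13);
  return out;
}

// Size-zone matrix: counts of 26-connected same-level zones by (level,
// zone size).  Returns nlev x maxsize matrix.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector lv, IntegerVector dims, int nlev) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int,int> > zones;  // (level, size)
  std::vector<int> stack;
  int maxsize = 1;
  for (int s = 0; s < n; ++s) {
    const int a = lv[s];
    if (!a || seen[s]) continue;
    int size = 0;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      const int v = stack.back(); stack.pop_back();
      ++size;
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            const int w = X + nx * (Y + ny * Z);
            if (!seen[w] && lv[w] == a) { seen[w] = 1; stack.push_back(w); }
          }
    }
    zones.push_back(std::make_pair(a, size));
    if (size > maxsize) maxsize = size;
  }
  NumericMatrix M(nlev, maxsize);
  for (size_t i = 0; i < zones.size(); ++i)
    M(zones[i].first - 1, zones[i].second - 1) += 1.0;
  return M;
}

// Dependence matrix: for each ROI voxel, the dependence size is 1 (the
// center) plus the number of 26-neighbours inside the ROI whose level
// differs from the center's by at most `alpha`.  Returns nlev x 27.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lv, IntegerVector dims, int nlev,
                       int alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix M(nlev, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int a = lv[x + nx * (y + ny * z)];
        if (!a) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int b = at(lv, x + dx, y + dy, z + dz, nx, ny, nz);
              if (b && std::abs(b - a) <= alpha) ++dep;
            }
        M(a - 1, dep - 1) += 1.0;
      }
  return M;
}

// Neighbouring gray-tone difference: per level i, n_i (voxel count among
// voxels having at least one ROI neighbour) and s_i (sum of |i - mean of
// valid 26-neighbour levels|).  Returns nlev x 2 (cols: n_i, s_i).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lv, IntegerVector dims, int nlev) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix M(nlev, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int a = lv[x + nx * (y + ny * z)];
        if (!a) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int b = at(lv, x + dx, y + dy, z + dz, nx, ny, nz);
              if (b) { sum += b; ++cnt; }
            }
        if (cnt > 0) {
          M(a - 1, 0) += 1.0;
          M(a - 1, 1) += std::fabs(a - sum / cnt);
        }
      }
  return M;
}
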