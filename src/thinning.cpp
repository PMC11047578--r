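// 3D topology-preserving sequential thinning and voxel utilities.
//
// Foreground connectivity is 26, background connectivity is 6 (the standard
// complementary pair).  A voxel is "simple" (deletable without changing
// topology) when its 3x3x3 neighbourhood satisfies the two Malandain-Bertrand
// conditions: exactly one 26-component of foreground in N26, and exactly one
// 6-component of background in N18 that touches a face neighbour.  Thinning
// removes simple, non-endpoint border voxels sequentially in six directional
// subcycles until stable, which preserves both topology and curve endpoints.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// 27-cell neighbourhood helpers; cell index = (dx+1) + 3*(dy+1) + 9*(dz+1)
inline int cellIndex(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

struct Grid {
  const std::vector<char>* v;
  int nx, ny, nz;
  bool at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return (*v)[x + nx * (y + (size_t)ny * z)] != 0;
  }
};

// fill nb[27] with the 3x3x3 neighbourhood of (x,y,z); out-of-volume = false
inline void neighbourhood(const Grid& g, int x, int y, int z, bool nb[27]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k)
        nb[k] = g.at(x + dx, y + dy, z + dz);
}

inline void cellCoords(int c, int& dx, int& dy, int& dz) {
  dx = c % 3 - 1;
  dy = (c / 3) % 3 - 1;
  dz = c / 9 - 1;
}

inline bool adj26(int a, int b) {
  int ax, ay, az, bx, by, bz;
  cellCoords(a, ax, ay, az);
  cellCoords(b, bx, by, bz);
  int mx = std::abs(ax - bx), my = std::abs(ay - by), mz = std::abs(az - bz);
  return (mx <= 1 && my <= 1 && mz <= 1) && (mx + my + mz > 0);
}

inline bool adj6(int a, int b) {
  int ax, ay, az, bx, by, bz;
  cellCoords(a, ax, ay, az);
  cellCoords(b, bx, by, bz);
  return std::abs(ax - bx) + std::abs(ay - by) + std::abs(az - bz) == 1;
}

inline int l1(int c) {
  int dx, dy, dz;
  cellCoords(c, dx, dy, dz);
  return std::abs(dx) + std::abs(dy) + std::abs(dz);
}

// number of 26-components of foreground among the 26 neighbours (centre excl.)
int fgComponents26(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> stack(1, s);
    seen[s] = true;
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || seen[t] || !nb[t]) continue;
        if (adj26(c, t)) {
          seen[t] = true;
          stack.push_back(t);
        }
      }
    }
  }
  return comps;
}

// number of 6-components of background restricted to N18 that contain a face
// neighbour of the centre
int bgComponents6(const bool nb[27]) {
  bool inN18[27], seen[27] = {false};
  for (int c = 0; c < 27; ++c) inN18[c] = (c != 13 && l1(c) <= 2);
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (!inN18[s] || nb[s] || seen[s] || l1(s) != 1) continue;  // seed: bg face nbr
    ++comps;
    std::vector<int> stack(1, s);
    seen[s] = true;
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      for (int t = 0; t < 27; ++t) {
        if (!inN18[t] || nb[t] || seen[t]) continue;
        if (adj6(c, t)) {
          seen[t] = true;
          stack.push_back(t);
        }
      }
    }
  }
  return comps;
}

inline int fgNeighbourCount(const bool nb[27]) {
  int n = 0;
  for (int c = 0; c < 27; ++c)
    if (c != 13 && nb[c]) ++n;
  return n;
}

inline bool isSimple(const bool nb[27]) {
  return fgComponents26(nb) == 1 && bgComponents6(nb) == 1;
}

}  // namespace

// [[Rcpp::export(name = ".thin_voxels_cpp")]]
LogicalVector thin_voxels_cpp(LogicalVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> v((size_t)nx * ny * nz);
  for (size_t i = 0; i < v.size(); ++i) v[i] = vol[i] ? 1 : 0;
  Grid g{&v, nx, ny, nz};

  // six directional subcycles: Up, Down, North, South, East, West
  const int dirs[6][3] = {{0, 0, 1},  {0, 0, -1}, {0, 1, 0},
                          {0, -1, 0}, {1, 0, 0},  {-1, 0, 0}};
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<size_t> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            size_t idx = x + nx * (y + (size_t)ny * z);
            if (!v[idx]) continue;
            if (g.at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
            neighbourhood(g, x, y, z, nb);
            if (fgNeighbourCount(nb) <= 1) continue;  // keep curve endpoints
            if (isSimple(nb)) cand.push_back(idx);
          }
      // sequential deletion: re-check simplicity at deletion time
      for (size_t idx : cand) {
        int x = (int)(idx % nx);
        int y = (int)((idx / nx) % ny);
        int z = (int)(idx / ((size_t)nx * ny));
        neighbourhood(g, x, y, z, nb);
        if (fgNeighbourCount(nb) <= 1) continue;
        if (isSimple(nb)) {
          v[idx] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalVector out(vol.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// Connected component count of the foreground (26- or 6-connectivity).
// [[Rcpp::export(name = ".count_components_cpp")]]
int count_components_cpp(LogicalVector vol, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> v((size_t)nx * ny * nz);
  for (size_t i = 0; i < v.size(); ++i) v[i] = vol[i] ? 1 : 0;
  std::vector<char> seen(v.size(), 0);
  int comps = 0;
  for (size_t start = 0; start < v.size(); ++start) {
    if (!v[start] || seen[start]) continue;
    ++comps;
    std::vector<size_t> stack(1, start);
    seen[start] = 1;
    while (!stack.empty()) {
      size_t idx = stack.back();
      stack.pop_back();
      int x = (int)(idx % nx);
      int y = (int)((idx / nx) % ny);
      int z = (int)(idx / ((size_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 &&
                std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            size_t j = xx + nx * (yy + (size_t)ny * zz);
            if (v[j] && !seen[j]) {
              seen[j] = 1;
              stack.push_back(j);
            }
          }
    }
  }
  return comps;
}
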