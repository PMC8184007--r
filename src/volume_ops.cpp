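#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Voxel grids arrive as R logical arrays in column-major order:
// linear index = x + nx*(y + ny*z), all 0-based here.

static inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// ---------------------------------------------------------------------------
// 26-connected component labeling (iterative flood fill).
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = vol.size();
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!vol[i] || lab[i]) continue;
    ++cur;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (!inside(xx, yy, zz, nx, ny, nz)) continue;
            R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (vol[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
          }
    }
  }
  lab.attr("n_labels") = cur;
  return lab;
}

// ---------------------------------------------------------------------------
// Count of occupied voxels in the 3x3x3 neighborhood (center included);
// out-of-bounds neighbors count as empty.
// [[Rcpp::export]]
IntegerVector neighbor_count_cpp(LogicalVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(vol.size(), 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (!inside(xx, yy, zz, nx, ny, nz)) continue;
              if (vol[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)]) ++cnt;
            }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = cnt;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point test (Malandain & Bertrand characterization):
//   (a) exactly one 26-connected component of object voxels among the 26
//       neighbors, and
//   (b) exactly one 6-connected component of background voxels in the
//       18-neighborhood that is 6-adjacent to the center.
// Neighborhood tables are built once.

namespace {

struct NbTables {
  int off[26][3];        // the 26 neighbor offsets
  bool adj26[26][26];    // 26-adjacency between neighbor positions
  int  n18idx[26];       // index into 18-subset or -1 (corners excluded)
  int  n18pos[18];       // positions (in 0..25) belonging to N18
  bool adj6[18][18];     // 6-adjacency within N18
  bool faceOf18[18];     // 6-adjacent to center?
  NbTables() {
    int k = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          off[k][0] = dx; off[k][1] = dy; off[k][2] = dz; ++k;
        }
    for (int i = 0; i < 26; ++i)
      for (int j = 0; j < 26; ++j) {
        int ax = std::abs(off[i][0] - off[j][0]);
        int ay = std::abs(off[i][1] - off[j][1]);
        int az = std::abs(off[i][2] - off[j][2]);
        adj26[i][j] = (i != j) && ax <= 1 && ay <= 1 && az <= 1;
      }
    int m = 0;
    for (int i = 0; i < 26; ++i) {
      int nz0 = std::abs(off[i][0]) + std::abs(off[i][1]) + std::abs(off[i][2]);
      if (nz0 <= 2) { n18idx[i] = m; n18pos[m] = i; ++m; }
      else n18idx[i] = -1;
    }
    for (int a = 0; a < 18; ++a) {
      int i = n18pos[a];
      faceOf18[a] = (std::abs(off[i][0]) + std::abs(off[i][1]) + std::abs(off[i][2])) == 1;
      for (int b = 0; b < 18; ++b) {
        int j = n18pos[b];
        int d = std::abs(off[i][0] - off[j][0]) + std::abs(off[i][1] - off[j][1]) +
                std::abs(off[i][2] - off[j][2]);
        adj6[a][b] = (a != b) && d == 1;
      }
    }
  }
};

const NbTables NT;

// nb[26]: occupancy of the 26 neighbors of a voxel.
bool is_simple(const bool *nb) {
  // (a) object components under 26-adjacency
  bool seen[26] = {false};
  int comps = 0;
  int stack[26], top;
  for (int i = 0; i < 26; ++i) {
    if (!nb[i] || seen[i]) continue;
    ++comps;
    if (comps > 1) return false;
    top = 0; stack[top++] = i; seen[i] = true;
    while (top) {
      int v = stack[--top];
      for (int j = 0; j < 26; ++j)
        if (nb[j] && !seen[j] && NT.adj26[v][j]) { seen[j] = true; stack[top++] = j; }
    }
  }
  if (comps != 1) return false;
  // (b) background 6-components in N18 touching the center
  bool seen18[18] = {false};
  int bg = 0;
  for (int a = 0; a < 18; ++a) {
    if (nb[NT.n18pos[a]] || seen18[a]) continue;
    // grow this background component
    int st[18], tp = 0;
    st[tp++] = a; seen18[a] = true;
    bool touches = false;
    while (tp) {
      int v = st[--tp];
      if (NT.faceOf18[v]) touches = true;
      for (int b = 0; b < 18; ++b)
        if (!nb[NT.n18pos[b]] && !seen18[b] && NT.adj6[v][b]) { seen18[b] = true; st[tp++] = b; }
    }
    if (touches) ++bg;
    if (bg > 1) return false;
  }
  return bg == 1;
}

inline void gather_nb(const std::vector<char> &occ, int x, int y, int z,
                      int nx, int ny, int nz, bool *nb) {
  for (int i = 0; i < 26; ++i) {
    int xx = x + NT.off[i][0], yy = y + NT.off[i][1], zz = z + NT.off[i][2];
    nb[i] = inside(xx, yy, zz, nx, ny, nz) &&
            occ[xx + (size_t)nx * (yy + (size_t)ny * zz)];
  }
}

} // namespace

// ---------------------------------------------------------------------------
// Medial-axis thinning: voxels are visited in increasing chamfer-distance
// order (deepest last) and removed sequentially while they remain simple
// points and are not curve endpoints; iterated to a fixpoint. Preserves the
// homotopy type of the object (a loop stays a loop) and leaves tubes as
// one-voxel-wide 26-connected paths.
// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> occ(n);
  for (size_t i = 0; i < n; ++i) occ[i] = vol[i] ? 1 : 0;

  // chamfer <3,4,5> distance to background (boundary faces treated as bg)
  std::vector<int> dist(n, 0);
  const int BIG = 1 << 28;
  for (size_t i = 0; i < n; ++i) dist[i] = occ[i] ? BIG : 0;
  auto w = [](int dx, int dy, int dz) {
    int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
    return s == 1 ? 3 : (s == 2 ? 4 : 5);
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t v = x + (size_t)nx * (y + (size_t)ny * z);
        if (!occ[v]) continue;
        int d = dist[v];
        bool border = false;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              if (dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0)))) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (!inside(xx, yy, zz, nx, ny, nz)) { border = true; continue; }
              size_t u = xx + (size_t)nx * (yy + (size_t)ny * zz);
              int cand = dist[u] + w(dx, dy, dz);
              if (cand < d) d = cand;
            }
        if (border && 3 < d) d = 3;
        dist[v] = d;
      }
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        size_t v = x + (size_t)nx * (y + (size_t)ny * z);
        if (!occ[v]) continue;
        int d = dist[v];
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              if (dz < 0 || (dz == 0 && (dy < 0 || (dy == 0 && dx < 0)))) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (!inside(xx, yy, zz, nx, ny, nz)) continue;
              size_t u = xx + (size_t)nx * (yy + (size_t)ny * zz);
              int cand = dist[u] + w(dx, dy, dz);
              if (cand < d) d = cand;
            }
        dist[v] = d;
      }

  std::vector<size_t> order;
  order.reserve(n / 8);
  for (size_t i = 0; i < n; ++i) if (occ[i]) order.push_back(i);
  std::stable_sort(order.begin(), order.end(),
                   [&dist](size_t a, size_t b) { return dist[a] < dist[b]; });

  bool nb[26];
  bool changed = true;
  while (changed) {
    changed = false;
    for (size_t k = 0; k < order.size(); ++k) {
      size_t v = order[k];
      if (!occ[v]) continue;
      int x = v % nx, y = (v / nx) % ny, z = v / ((size_t)nx * ny);
      gather_nb(occ, x, y, z, nx, ny, nz, nb);
      int nnb = 0;
      for (int i = 0; i < 26; ++i) nnb += nb[i];
      if (nnb <= 1) continue;            // endpoint (or isolated): keep
      if (!is_simple(nb)) continue;
      occ[v] = 0;
      changed = true;
    }
  }

  LogicalVector out(vol.size());
  for (size_t i = 0; i < n; ++i) out[i] = occ[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Rejection placement: draw anchor voxels uniformly from `anchors0` (0-based
// linear indices) until the object given by `offsets` (k x 3, voxel offsets
// relative to the anchor) fits entirely inside `mask` without touching
// `occupied`. Returns the 0-based anchor index, or -1 after max_tries.
// Uses R's RNG so placements are reproducible under set.seed().
// [[Rcpp::export]]
int try_place_cpp(LogicalVector mask, LogicalVector occupied, IntegerVector dims,
                  IntegerMatrix offsets, IntegerVector anchors0, int max_tries) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int k = offsets.nrow();
  const int na = anchors0.size();
  if (na == 0) return -1;
  for (int t = 0; t < max_tries; ++t) {
    int j = (int)(unif_rand() * na);
    if (j >= na) j = na - 1;
    R_xlen_t a = anchors0[j];
    int ax = a % nx, ay = (a / nx) % ny, az = a / ((R_xlen_t)nx * ny);
    bool ok = true;
    for (int i = 0; i < k && ok; ++i) {
      int x = ax + offsets(i, 0), y = ay + offsets(i, 1), z = az + offsets(i, 2);
      if (!inside(x, y, z, nx, ny, nz)) { ok = false; break; }
      R_xlen_t v = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      if (!mask[v] || occupied[v]) ok = false;
    }
    if (ok) return (int)a;
  }
  return -1;
}
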