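#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Voxel morphology on 3-D grids stored in R's column-major order
// (index = x + nx*(y + ny*z), all 0-based here).

static inline long long lin(int x, int y, int z, int nx, int ny) {
  return (long long)x + (long long)nx * ((long long)y + (long long)ny * z);
}

// offsets for 6- and 26-connectivity
static const int OFF6[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
};

static void offsets26(int off[26][3]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        off[k][0] = dx; off[k][1] = dy; off[k][2] = dz; ++k;
      }
}

// [[Rcpp::export]]
LogicalVector cpp_flood_fill(NumericVector vals, IntegerVector dim,
                             IntegerVector seed, double threshold,
                             int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long long n = (long long)nx * ny * nz;
  std::vector<char> out(n, 0);
  LogicalVector res(n);
  int sx = seed[0], sy = seed[1], sz = seed[2];
  if (sx < 0 || sy < 0 || sz < 0 || sx >= nx || sy >= ny || sz >= nz)
    stop("seed outside volume");
  long long s = lin(sx, sy, sz, nx, ny);
  if (!(vals[s] < threshold)) { // nothing to grow
    res.attr("dim") = dim;
    return res;
  }
  int off26[26][3]; offsets26(off26);
  const int nof = (connectivity == 6) ? 6 : 26;
  std::queue<long long> q;
  out[s] = 1; q.push(s);
  while (!q.empty()) {
    long long c = q.front(); q.pop();
    int cz = (int)(c / ((long long)nx * ny));
    long long r = c - (long long)cz * nx * ny;
    int cy = (int)(r / nx), cx = (int)(r % nx);
    for (int k = 0; k < nof; ++k) {
      int dx, dy, dz;
      if (connectivity == 6) { dx = OFF6[k][0]; dy = OFF6[k][1]; dz = OFF6[k][2]; }
      else { dx = off26[k][0]; dy = off26[k][1]; dz = off26[k][2]; }
      int x = cx + dx, y = cy + dy, z = cz + dz;
      if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
      long long t = lin(x, y, z, nx, ny);
      if (!out[t] && vals[t] < threshold) { out[t] = 1; q.push(t); }
    }
  }
  for (long long i = 0; i < n; ++i) res[i] = out[i] != 0;
  res.attr("dim") = dim;
  return res;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long long n = (long long)nx * ny * nz;
  IntegerVector lab(n);
  int off26[26][3]; offsets26(off26);
  const int nof = (connectivity == 6) ? 6 : 26;
  int cur = 0;
  std::queue<long long> q;
  for (long long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur; lab[i] = cur; q.push(i);
    while (!q.empty()) {
      long long c = q.front(); q.pop();
      int cz = (int)(c / ((long long)nx * ny));
      long long r = c - (long long)cz * nx * ny;
      int cy = (int)(r / nx), cx = (int)(r % nx);
      for (int k = 0; k < nof; ++k) {
        int dx, dy, dz;
        if (connectivity == 6) { dx = OFF6[k][0]; dy = OFF6[k][1]; dz = OFF6[k][2]; }
        else { dx = off26[k][0]; dy = off26[k][1]; dz = off26[k][2]; }
        int x = cx + dx, y = cy + dy, z = cz + dz;
        if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
        long long t = lin(x, y, z, nx, ny);
        if (mask[t] && !lab[t]) { lab[t] = cur; q.push(t); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ---- topology-preserving 3-D thinning ------------------------------------
// Sequential directional thinning deleting simple, non-endpoint border
// points. Simpleness by the Bertrand/Malandain characterization:
//   T26 = number of 26-components of the object within N26*  == 1
//   T6  = number of 6-components of the background within N18 that are
//         6-adjacent to the center == 1

static inline bool in3(int v) { return v >= 0 && v < 3; }

// occupancy of 3x3x3 neighborhood as nb[x][y][z], center at (1,1,1)
static bool is_simple(const char nb[3][3][3]) {
  // T26 on object neighbors (center excluded)
  int idx_of[27]; int cnt = 0;
  int pts[27][3];
  for (int z = 0; z < 3; ++z) for (int y = 0; y < 3; ++y) for (int x = 0; x < 3; ++x) {
    if (x == 1 && y == 1 && z == 1) continue;
    if (nb[x][y][z]) { pts[cnt][0] = x; pts[cnt][1] = y; pts[cnt][2] = z; ++cnt; }
  }
  (void)idx_of;
  if (cnt == 0) return false;
  // BFS over 26-adjacency among pts
  std::vector<char> vis(cnt, 0);
  std::vector<int> st; st.push_back(0); vis[0] = 1;
  int seen = 1;
  while (!st.empty()) {
    int c = st.back(); st.pop_back();
    for (int j = 0; j < cnt; ++j) {
      if (vis[j]) continue;
      int dx = std::abs(pts[c][0] - pts[j][0]);
      int dy = std::abs(pts[c][1] - pts[j][1]);
      int dz = std::abs(pts[c][2] - pts[j][2]);
      if (dx <= 1 && dy <= 1 && dz <= 1) { vis[j] = 1; st.push_back(j); ++seen; }
    }
  }
  if (seen != cnt) return false;
  // T6: background voxels in N18, 6-components 6-adjacent to center
  int bg[27][3]; int bcnt = 0;
  for (int z = 0; z < 3; ++z) for (int y = 0; y < 3; ++y) for (int x = 0; x < 3; ++x) {
    if (x == 1 && y == 1 && z == 1) continue;
    int man = std::abs(x - 1) + std::abs(y - 1) + std::abs(z - 1);
    if (man > 2) continue;               // N18 only
    if (!nb[x][y][z]) { bg[bcnt][0] = x; bg[bcnt][1] = y; bg[bcnt][2] = z; ++bcnt; }
  }
  if (bcnt == 0) return false;
  std::vector<char> bvis(bcnt, 0);
  int ncomp_adj = 0;
  for (int i = 0; i < bcnt; ++i) {
    if (bvis[i]) continue;
    // new component: BFS with 6-adjacency restricted to N18 set
    std::vector<int> stk; stk.push_back(i); bvis[i] = 1;
    bool adj_center = false;
    while (!stk.empty()) {
      int c = stk.back(); stk.pop_back();
      int man = std::abs(bg[c][0] - 1) + std::abs(bg[c][1] - 1) + std::abs(bg[c][2] - 1);
      if (man == 1) adj_center = true;
      for (int j = 0; j < bcnt; ++j) {
        if (bvis[j]) continue;
        int dd = std::abs(bg[c][0] - bg[j][0]) + std::abs(bg[c][1] - bg[j][1]) +
                 std::abs(bg[c][2] - bg[j][2]);
        if (dd == 1) { bvis[j] = 1; stk.push_back(j); }
      }
    }
    if (adj_center) ++ncomp_adj;
  }
  return ncomp_adj == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long long n = (long long)nx * ny * nz;
  std::vector<char> m(n);
  for (long long i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  int off26[26][3]; offsets26(off26);

  auto val = [&](int x, int y, int z) -> char {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return m[lin(x, y, z, nx, ny)];
  };
  auto nb26count = [&](int x, int y, int z) {
    int c = 0;
    for (int k = 0; k < 26; ++k)
      c += val(x + off26[k][0], y + off26[k][1], z + off26[k][2]);
    return c;
  };
  auto fill_nb = [&](int x, int y, int z, char nb[3][3][3]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[dx + 1][dy + 1][dz + 1] = val(x + dx, y + dy, z + dz);
  };

  bool changed = true;
  std::vector<long long> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
        long long i = lin(x, y, z, nx, ny);
        if (!m[i]) continue;
        // border in direction d
        if (val(x + OFF6[d][0], y + OFF6[d][1], z + OFF6[d][2])) continue;
        if (nb26count(x, y, z) <= 1) continue;   // endpoint preserved
        char nb[3][3][3]; fill_nb(x, y, z, nb);
        if (is_simple(nb)) cand.push_back(i);
      }
      // sequential deletion with re-check keeps topology exact
      for (size_t k = 0; k < cand.size(); ++k) {
        long long i = cand[k];
        int z = (int)(i / ((long long)nx * ny));
        long long r = i - (long long)z * nx * ny;
        int y = (int)(r / nx), x = (int)(r % nx);
        if (nb26count(x, y, z) <= 1) continue;
        char nb[3][3][3]; fill_nb(x, y, z, nb);
        if (!is_simple(nb)) continue;
        m[i] = 0; changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (long long i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vals, IntegerVector dim,
                                NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long long n = (long long)nx * ny * nz;
  std::vector<double> a(vals.begin(), vals.end()), b(n);
  const int dims[3] = {nx, ny, nz};
  const long long strides[3] = {1, nx, (long long)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * rad + 1);
    double sum = 0;
    for (int k = -rad; k <= rad; ++k) { ker[k + rad] = std::exp(-0.5 * k * k / (s * s)); sum += ker[k + rad]; }
    for (double &v : ker) v /= sum;
    int nd = dims[ax];
    long long st = strides[ax];
    // iterate over all lines along axis ax
    for (long long i = 0; i < n; ++i) {
      // coordinate along axis
      long long c = (i / st) % nd;
      double acc = 0;
      for (int k = -rad; k <= rad; ++k) {
        long long cc = c + k;
        if (cc < 0) cc = -cc;                       // reflect
        if (cc >= nd) cc = 2 * (nd - 1) - cc;
        acc += ker[k + rad] * a[i + (cc - c) * st];
      }
      b[i] = acc;
    }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// nearest reference point (brute force); vox and pts in the same (mm)
// coordinate system; returns 1-based index of nearest pt per row of vox
// [[Rcpp::export]]
IntegerVector cpp_nearest_point(NumericMatrix vox, NumericMatrix pts) {
  const int n = vox.nrow(), m = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int bj = 1;
    double x = vox(i, 0), y = vox(i, 1), z = vox(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = x - pts(j, 0), dy = y - pts(j, 1), dz = z - pts(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j + 1; }
    }
    out[i] = bj;
  }
  return out;
}
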