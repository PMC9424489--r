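#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Volumes are stored (z, y, x) with z fastest: linear index = z + nz*(y + ny*x).
// All scans run in lexicographic (z, y, x) order (z slowest) so label order and
// thinning are bit-reproducible and translation invariant.

struct Grid {
  int nz, ny, nx;
  Grid(const IntegerVector &d) : nz(d[0]), ny(d[1]), nx(d[2]) {}
  inline R_xlen_t idx(int z, int y, int x) const {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  }
  inline bool inside(int z, int y, int x) const {
    return z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
  }
  R_xlen_t size() const { return (R_xlen_t)nz * ny * nx; }
};

static void conn_offsets(int conn, std::vector<std::array<int,3>> &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dz && !dy && !dx) continue;
        int s = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (conn == 6 && s > 1) continue;
        if (conn == 18 && s > 2) continue;
        off.push_back({dz, dy, dx});
      }
}

// decode linear index back to (z,y,x)
static inline void coords(R_xlen_t i, const Grid &g, int &z, int &y, int &x) {
  z = (int)(i % g.nz);
  R_xlen_t r = i / g.nz;
  y = (int)(r % g.ny);
  x = (int)(r / g.ny);
}

// [[Rcpp::export]]
LogicalVector cpp_hysteresis(NumericVector vol, IntegerVector dims,
                             double low, double high, int conn) {
  Grid g(dims);
  std::vector<std::array<int,3>> off;
  conn_offsets(conn, off);
  R_xlen_t n = g.size();
  std::vector<char> out(n, 0);
  std::queue<R_xlen_t> q;
  // seed from strong voxels in lex (z,y,x) order
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        R_xlen_t i = g.idx(z, y, x);
        if (vol[i] >= high && !out[i]) { out[i] = 1; q.push(i); }
      }
  while (!q.empty()) {
    R_xlen_t i = q.front(); q.pop();
    int z, y, x; coords(i, g, z, y, x);
    for (auto &o : off) {
      int zz = z + o[0], yy = y + o[1], xx = x + o[2];
      if (!g.inside(zz, yy, xx)) continue;
      R_xlen_t j = g.idx(zz, yy, xx);
      if (!out[j] && vol[j] >= low) { out[j] = 1; q.push(j); }
    }
  }
  LogicalVector res(n);
  for (R_xlen_t i = 0; i < n; ++i) res[i] = out[i] != 0;
  res.attr("dim") = dims;
  return res;
}

// [[Rcpp::export]]
List cpp_label_components(LogicalVector mask, IntegerVector dims, int conn) {
  Grid g(dims);
  std::vector<std::array<int,3>> off;
  conn_offsets(conn, off);
  R_xlen_t n = g.size();
  IntegerVector labels(n, 0);
  std::vector<int> sizes;
  int next = 0;
  std::queue<R_xlen_t> q;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        R_xlen_t i = g.idx(z, y, x);
        if (!mask[i] || labels[i]) continue;
        ++next;
        int sz = 0;
        labels[i] = next; q.push(i);
        while (!q.empty()) {
          R_xlen_t c = q.front(); q.pop(); ++sz;
          int cz, cy, cx; coords(c, g, cz, cy, cx);
          for (auto &o : off) {
            int zz = cz + o[0], yy = cy + o[1], xx = cx + o[2];
            if (!g.inside(zz, yy, xx)) continue;
            R_xlen_t j = g.idx(zz, yy, xx);
            if (mask[j] && !labels[j]) { labels[j] = next; q.push(j); }
          }
        }
        sizes.push_back(sz);
      }
  labels.attr("dim") = dims;
  return List::create(_["labels"] = labels,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), spacing h.
static void dt1d(const double *f, double *d, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = -INFINITY; zb[1] = INFINITY;
  double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    d[q] = h2 * (q - p) * (q - p) + f[p];
  }
}

// Squared Euclidean distance (um^2) from each voxel to the nearest background
// voxel centre. If pad_bg, the outside of the grid counts as background one
// voxel step away along each axis.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         double hz, double hy, double hx, bool pad_bg) {
  Grid g(dims);
  int pz = g.nz + 2, py = g.ny + 2, px = g.nx + 2;
  R_xlen_t np = (R_xlen_t)pz * py * px;
  std::vector<double> d(np);
  const double INF = 1e30;
  // build padded field: 0 at background (and border if pad_bg), INF at foreground
  for (int x = 0; x < px; ++x)
    for (int y = 0; y < py; ++y)
      for (int z = 0; z < pz; ++z) {
        R_xlen_t i = (R_xlen_t)z + (R_xlen_t)pz * ((R_xlen_t)y + (R_xlen_t)py * x);
        bool border = (z == 0 || y == 0 || x == 0 || z == pz - 1 || y == py - 1 || x == px - 1);
        if (border) { d[i] = pad_bg ? 0.0 : INF; continue; }
        d[i] = mask[g.idx(z - 1, y - 1, x - 1)] ? INF : 0.0;
      }
  std::vector<double> f(std::max(std::max(pz, py), px)), o(std::max(std::max(pz, py), px));
  // z pass
  for (int x = 0; x < px; ++x)
    for (int y = 0; y < py; ++y) {
      R_xlen_t base = (R_xlen_t)pz * ((R_xlen_t)y + (R_xlen_t)py * x);
      for (int z = 0; z < pz; ++z) f[z] = d[base + z];
      dt1d(f.data(), o.data(), pz, hz);
      for (int z = 0; z < pz; ++z) d[base + z] = o[z];
    }
  // y pass
  for (int x = 0; x < px; ++x)
    for (int z = 0; z < pz; ++z) {
      for (int y = 0; y < py; ++y) f[y] = d[(R_xlen_t)z + (R_xlen_t)pz * ((R_xlen_t)y + (R_xlen_t)py * x)];
      dt1d(f.data(), o.data(), py, hy);
      for (int y = 0; y < py; ++y) d[(R_xlen_t)z + (R_xlen_t)pz * ((R_xlen_t)y + (R_xlen_t)py * x)] = o[y];
    }
  // x pass
  for (int y = 0; y < py; ++y)
    for (int z = 0; z < pz; ++z) {
      for (int x = 0; x < px; ++x) f[x] = d[(R_xlen_t)z + (R_xlen_t)pz * ((R_xlen_t)y + (R_xlen_t)py * x)];
      dt1d(f.data(), o.data(), px, hx);
      for (int x = 0; x < px; ++x) d[(R_xlen_t)z + (R_xlen_t)pz * ((R_xlen_t)y + (R_xlen_t)py * x)] = o[x];
    }
  NumericVector out(g.size());
  for (int x = 0; x < g.nx; ++x)
    for (int y = 0; y < g.ny; ++y)
      for (int z = 0; z < g.nz; ++z)
        out[g.idx(z, y, x)] = d[(R_xlen_t)(z + 1) + (R_xlen_t)pz * ((R_xlen_t)(y + 1) + (R_xlen_t)py * (x + 1))];
  out.attr("dim") = dims;
  return out;
}

// ---- homotopic thinning -------------------------------------------------

// adjacency tables on the 3x3x3 cell lattice, built once
static std::vector<std::vector<int>> adj26_tab, adj6_tab;
static bool is18_tab[27];
static bool tabs_ready = false;

static void build_tabs() {
  if (tabs_ready) return;
  adj26_tab.assign(27, {});
  adj6_tab.assign(27, {});
  for (int a = 0; a < 27; ++a) {
    int az = a / 9 - 1, ay = (a / 3) % 3 - 1, ax = a % 3 - 1;
    int s = std::abs(az) + std::abs(ay) + std::abs(ax);
    is18_tab[a] = (s >= 1 && s <= 2);
    for (int b = 0; b < 27; ++b) {
      if (a == b) continue;
      int bz = b / 9 - 1, by = (b / 3) % 3 - 1, bx = b % 3 - 1;
      int dz = std::abs(az - bz), dy = std::abs(ay - by), dx = std::abs(ax - bx);
      if (dz <= 1 && dy <= 1 && dx <= 1) adj26_tab[a].push_back(b);
      if (dz + dy + dx == 1) adj6_tab[a].push_back(b);
    }
  }
  tabs_ready = true;
}

// N[27]: foreground flags of the 3x3x3 neighbourhood, centre at 13.
static int count_fg26(const bool *N) {
  int c = 0;
  for (int a = 0; a < 27; ++a) if (a != 13 && N[a]) ++c;
  return c;
}

// number of 26-components of foreground among the 26 neighbours
static int cc26_fg(const bool *N) {
  bool seen[27] = {false};
  int comps = 0;
  for (int a = 0; a < 27; ++a) {
    if (a == 13 || !N[a] || seen[a]) continue;
    ++comps;
    std::vector<int> st{a};
    seen[a] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      for (int b : adj26_tab[c]) {
        if (b == 13 || !N[b] || seen[b]) continue;
        seen[b] = true; st.push_back(b);
      }
    }
  }
  return comps;
}

// number of 6-components of background within the 18-neighbourhood that are
// 6-adjacent to the centre (i.e. contain a face neighbour)
static int cc6_bg(const bool *N) {
  bool seen[27] = {false};
  int comps = 0;
  for (int a : adj6_tab[13]) { // the 6 face neighbours
    if (N[a] || seen[a]) continue;
    ++comps;
    std::vector<int> st{a};
    seen[a] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      for (int b : adj6_tab[c]) {
        if (b == 13 || !is18_tab[b] || N[b] || seen[b]) continue;
        seen[b] = true; st.push_back(b);
      }
    }
  }
  return comps;
}

static inline void fill_nbhd(const std::vector<char> &img, const Grid &g,
                             int z, int y, int x, bool *N) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        N[k] = g.inside(zz, yy, xx) && img[g.idx(zz, yy, xx)];
      }
}

static inline bool simple_point(const std::vector<char> &img, const Grid &g,
                                int z, int y, int x) {
  bool N[27];
  fill_nbhd(img, g, z, y, x, N);
  if (count_fg26(N) <= 1) return false; // curve endpoint: keep
  return cc26_fg(N) == 1 && cc6_bg(N) == 1;
}

// Homotopic 3D thinning to a unit-width medial structure; curve endpoints are
// preserved. Six directional subiterations per pass; deletions are sequential
// with re-testing, so topology is preserved exactly.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dims) {
  build_tabs();
  Grid g(dims);
  R_xlen_t n = g.size();
  std::vector<char> img(n, 0);
  std::vector<R_xlen_t> fg;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        R_xlen_t i = g.idx(z, y, x);
        if (mask[i]) { img[i] = 1; fg.push_back(i); }
      }
  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  bool changed = true;
  int guard = 0;
  std::vector<R_xlen_t> cand;
  while (changed && ++guard <= 500) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (R_xlen_t i : fg) {
        if (!img[i]) continue;
        int z, y, x; coords(i, g, z, y, x);
        int zz = z + dirs[d][0], yy = y + dirs[d][1], xx = x + dirs[d][2];
        bool bg_at_dir = !g.inside(zz, yy, xx) || !img[g.idx(zz, yy, xx)];
        if (bg_at_dir && simple_point(img, g, z, y, x)) cand.push_back(i);
      }
      for (R_xlen_t i : cand) {
        int z, y, x; coords(i, g, z, y, x);
        if (simple_point(img, g, z, y, x)) { img[i] = 0; changed = true; }
      }
    }
    // compact the foreground list
    std::vector<R_xlen_t> keep;
    keep.reserve(fg.size());
    for (R_xlen_t i : fg) if (img[i]) keep.push_back(i);
    fg.swap(keep);
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// separable Gaussian blur, sigmas in voxel units; kernel renormalised at borders
// [[Rcpp::export]]
NumericVector cpp_blur_sep(NumericVector vol, IntegerVector dims,
                           double sz, double sy, double sx) {
  Grid g(dims);
  R_xlen_t n = g.size();
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  double sig[3] = {sz, sy, sx};
  int dimlen[3] = {g.nz, g.ny, g.nx};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sig[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.5 * s));
    std::vector<double> k(2 * r + 1);
    double tot = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); tot += k[i + r]; }
    for (auto &v : k) v /= tot;
    int nlen = dimlen[ax];
    // stride of this axis
    R_xlen_t stride = (ax == 0) ? 1 : (ax == 1) ? (R_xlen_t)g.nz : (R_xlen_t)g.nz * g.ny;
    // iterate over all lines along axis ax
    int o1 = (ax == 0) ? g.ny : g.nz;
    int o2 = (ax == 2) ? g.ny : g.nx;
    R_xlen_t s1 = (ax == 0) ? (R_xlen_t)g.nz : 1;
    R_xlen_t s2 = (ax == 2) ? (R_xlen_t)g.nz : (R_xlen_t)g.nz * g.ny;
    for (int i1 = 0; i1 < o1; ++i1)
      for (int i2 = 0; i2 < o2; ++i2) {
        R_xlen_t base = s1 * i1 + s2 * i2;
        for (int p = 0; p < nlen; ++p) {
          double acc = 0, wsum = 0;
          int lo = std::max(0, p - r), hi = std::min(nlen - 1, p + r);
          for (int q = lo; q <= hi; ++q) {
            double w = k[q - p + r];
            acc += w * a[base + stride * q];
            wsum += w;
          }
          b[base + stride * p] = acc / wsum;
        }
      }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// mark voxels whose centre lies within rad[i] of point i (points in um, z/y/x)
// [[Rcpp::export]]
LogicalVector cpp_stamp_tubes(IntegerVector dims, double hz, double hy, double hx,
                              NumericMatrix pts, NumericVector rad) {
  Grid g(dims);
  R_xlen_t n = g.size();
  std::vector<char> out(n, 0);
  for (int i = 0; i < pts.nrow(); ++i) {
    double pz = pts(i, 0), py = pts(i, 1), px = pts(i, 2), r = rad[i];
    double r2 = r * r;
    int z0 = std::max(0, (int)std::ceil((pz - r) / hz));
    int z1 = std::min(g.nz - 1, (int)std::floor((pz + r) / hz));
    int y0 = std::max(0, (int)std::ceil((py - r) / hy));
    int y1 = std::min(g.ny - 1, (int)std::floor((py + r) / hy));
    int x0 = std::max(0, (int)std::ceil((px - r) / hx));
    int x1 = std::min(g.nx - 1, (int)std::floor((px + r) / hx));
    for (int x = x0; x <= x1; ++x) {
      double dx = x * hx - px;
      for (int y = y0; y <= y1; ++y) {
        double dy = y * hy - py;
        double dxy = dx * dx + dy * dy;
        if (dxy > r2) continue;
        for (int z = z0; z <= z1; ++z) {
          double dz = z * hz - pz;
          if (dxy + dz * dz <= r2) out[g.idx(z, y, x)] = 1;
        }
      }
    }
  }
  LogicalVector res(n);
  for (R_xlen_t i = 0; i < n; ++i) res[i] = out[i] != 0;
  res.attr("dim") = dims;
  return res;
}

// add background + Gaussian noise (R's RNG), clip to [0, cap], round to counts
// [[Rcpp::export]]
NumericVector cpp_finalize_volume(NumericVector vol, double bg, double sd,
                                  double cap) {
  R_xlen_t n = vol.size();
  NumericVector out(n);
  if (sd > 0) {
    GetRNGstate();
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = vol[i] + bg + R::rnorm(0.0, sd);
      out[i] = std::round(std::min(cap, std::max(0.0, v)));
    }
    PutRNGstate();
  } else {
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = vol[i] + bg;
      out[i] = std::round(std::min(cap, std::max(0.0, v)));
    }
  }
  out.attr("dim") = vol.attr("dim");
  return out;
}
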