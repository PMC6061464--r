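#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 3D Delaunay tetrahedralization (incremental Bowyer-Watson) and the
// alpha-complex built on it.  Points are expected in general position;
// callers jitter regular-grid inputs (see R/features.R).

namespace {

struct Tet {
  int v[4];
  double cx, cy, cz, r2;   // circumsphere
  bool alive;
};

inline double dist2(double ax, double ay, double az,
                    double bx, double by, double bz) {
  double dx = ax - bx, dy = ay - by, dz = az - bz;
  return dx * dx + dy * dy + dz * dz;
}

// circumsphere of 4 points via the linearized system
// 2 (p_i - p_0) . c = |p_i|^2 - |p_0|^2 ; returns false when flat
bool circumsphere(const std::vector<double>& px,
                  const std::vector<double>& py,
                  const std::vector<double>& pz,
                  const int v[4], double& cx, double& cy, double& cz,
                  double& r2) {
  double a[3][3], b[3];
  for (int i = 0; i < 3; ++i) {
    a[i][0] = 2.0 * (px[v[i + 1]] - px[v[0]]);
    a[i][1] = 2.0 * (py[v[i + 1]] - py[v[0]]);
    a[i][2] = 2.0 * (pz[v[i + 1]] - pz[v[0]]);
    b[i] = (px[v[i + 1]] * px[v[i + 1]] - px[v[0]] * px[v[0]]) +
           (py[v[i + 1]] * py[v[i + 1]] - py[v[0]] * py[v[0]]) +
           (pz[v[i + 1]] * pz[v[i + 1]] - pz[v[0]] * pz[v[0]]);
  }
  double det = a[0][0] * (a[1][1] * a[2][2] - a[1][2] * a[2][1]) -
               a[0][1] * (a[1][0] * a[2][2] - a[1][2] * a[2][0]) +
               a[0][2] * (a[1][0] * a[2][1] - a[1][1] * a[2][0]);
  if (std::fabs(det) < 1e-12) return false;
  double inv = 1.0 / det;
  cx = inv * (b[0] * (a[1][1] * a[2][2] - a[1][2] * a[2][1]) -
              a[0][1] * (b[1] * a[2][2] - a[1][2] * b[2]) +
              a[0][2] * (b[1] * a[2][1] - a[1][1] * b[2]));
  cy = inv * (a[0][0] * (b[1] * a[2][2] - a[1][2] * b[2]) -
              b[0] * (a[1][0] * a[2][2] - a[1][2] * a[2][0]) +
              a[0][2] * (a[1][0] * b[2] - b[1] * a[2][0]));
  cz = inv * (a[0][0] * (a[1][1] * b[2] - b[1] * a[2][1]) -
              a[0][1] * (a[1][0] * b[2] - b[1] * a[2][0]) +
              b[0] * (a[1][0] * a[2][1] - a[1][1] * a[2][0]));
  r2 = dist2(cx, cy, cz, px[v[0]], py[v[0]], pz[v[0]]);
  return true;
}

double tet_volume(const std::vector<double>& px,
                  const std::vector<double>& py,
                  const std::vector<double>& pz, const int v[4]) {
  double ax = px[v[1]] - px[v[0]], ay = py[v[1]] - py[v[0]],
         az = pz[v[1]] - pz[v[0]];
  double bx = px[v[2]] - px[v[0]], by = py[v[2]] - py[v[0]],
         bz = pz[v[2]] - pz[v[0]];
  double cx = px[v[3]] - px[v[0]], cy = py[v[3]] - py[v[0]],
         cz = pz[v[3]] - pz[v[0]];
  double det = ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
               az * (bx * cy - by * cx);
  return std::fabs(det) / 6.0;
}

double tri_area(const std::vector<double>& px, const std::vector<double>& py,
                const std::vector<double>& pz, int a, int b, int c) {
  double ux = px[b] - px[a], uy = py[b] - py[a], uz = pz[b] - pz[a];
  double vx = px[c] - px[a], vy = py[c] - py[a], vz = pz[c] - pz[a];
  double wx = uy * vz - uz * vy, wy = uz * vx - ux * vz,
         wz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(wx * wx + wy * wy + wz * wz);
}

std::vector<Tet> delaunay(std::vector<double>& px, std::vector<double>& py,
                          std::vector<double>& pz) {
  int n = (int)px.size();
  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0],
         zmin = pz[0], zmax = pz[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
    zmin = std::min(zmin, pz[i]); zmax = std::max(zmax, pz[i]);
  }
  // translate to the bbox center: reduces cancellation in the
  // circumsphere solve for near-degenerate (grid) configurations
  double tx = 0.5 * (xmin + xmax), ty = 0.5 * (ymin + ymax),
         tz = 0.5 * (zmin + zmax);
  for (int i = 0; i < n; ++i) { px[i] -= tx; py[i] -= ty; pz[i] -= tz; }
  xmin -= tx; xmax -= tx; ymin -= ty; ymax -= ty; zmin -= tz; zmax -= tz;
  double span = std::max({xmax - xmin, ymax - ymin, zmax - zmin, 1.0});
  double mx = 0.0, my = 0.0, mz = 0.0;
  double s = 500.0 * span;
  // enclosing super-tetrahedron, vertices n..n+3
  px.push_back(mx);      py.push_back(my);      pz.push_back(mz + 3 * s);
  px.push_back(mx - 2 * s); py.push_back(my - s); pz.push_back(mz - s);
  px.push_back(mx + 2 * s); py.push_back(my - s); pz.push_back(mz - s);
  px.push_back(mx);      py.push_back(my + 2 * s); pz.push_back(mz - s);

  std::vector<Tet> tets;
  {
    Tet t; t.v[0] = n; t.v[1] = n + 1; t.v[2] = n + 2; t.v[3] = n + 3;
    t.alive = true;
    if (!circumsphere(px, py, pz, t.v, t.cx, t.cy, t.cz, t.r2))
      stop("degenerate super-tetrahedron");
    tets.push_back(t);
  }

  typedef std::array<int, 3> Face;
  for (int p = 0; p < n; ++p) {
    // cavity = tets whose circumsphere contains p (brute scan)
    std::map<Face, int> face_count;
    std::vector<Face> faces;
    bool found = false;
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      double d2 = dist2(px[p], py[p], pz[p], tets[t].cx, tets[t].cy,
                        tets[t].cz);
      if (d2 <= tets[t].r2 * (1.0 + 1e-12)) {
        found = true;
        tets[t].alive = false;
        static const int fi[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3},
                                     {1, 2, 3}};
        for (int f = 0; f < 4; ++f) {
          Face fa = {tets[t].v[fi[f][0]], tets[t].v[fi[f][1]],
                     tets[t].v[fi[f][2]]};
          std::sort(fa.begin(), fa.end());
          int& c = face_count[fa];
          if (c == 0) faces.push_back(fa);
          ++c;
        }
      }
    }
    if (!found) stop("Delaunay insertion failed (degenerate input?)");
    // boundary faces appear exactly once; connect each to p
    for (const Face& fa : faces) {
      if (face_count[fa] != 1) continue;
      Tet t; t.v[0] = fa[0]; t.v[1] = fa[1]; t.v[2] = fa[2]; t.v[3] = p;
      t.alive = true;
      if (!circumsphere(px, py, pz, t.v, t.cx, t.cy, t.cz, t.r2)) {
        // numerically flat sliver: huge sphere so the next insertion
        // removes it
        t.cx = px[fa[0]]; t.cy = py[fa[0]]; t.cz = pz[fa[0]];
        t.r2 = 1e300;
      }
      tets.push_back(t);
    }
    // compact occasionally to keep the brute scan affordable
    if (tets.size() > 4096) {
      size_t dead = 0;
      for (const Tet& t : tets) if (!t.alive) ++dead;
      if (dead > tets.size() / 2) {
        std::vector<Tet> keep;
        keep.reserve(tets.size() - dead);
        for (const Tet& t : tets) if (t.alive) keep.push_back(t);
        tets.swap(keep);
      }
    }
  }
  std::vector<Tet> out;
  for (const Tet& t : tets) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    out.push_back(t);
  }
  return out;
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[a] = b;
    return true;
  }
};

}  // namespace

// [[Rcpp::export(name = ".delaunay_tets")]]
IntegerMatrix delaunay_tets_cpp(NumericMatrix points) {
  int n = points.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = points(i, 0); py[i] = points(i, 1); pz[i] = points(i, 2);
  }
  std::vector<Tet> tets = delaunay(px, py, pz);
  IntegerMatrix out(tets.size(), 4);
  for (size_t t = 0; t < tets.size(); ++t)
    for (int j = 0; j < 4; ++j) out(t, j) = tets[t].v[j] + 1;
  return out;
}

// Alpha complex at `scale` times the critical (smallest) alpha for which
// the complex contains every input point and forms a single face-connected
// region. Returns volume, surface area, the critical and used alpha, and
// tetra count.
// [[Rcpp::export(name = ".alpha_shape_cpp")]]
List alpha_shape_cpp(NumericMatrix points, double scale = 1.0) {
  int n = points.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = points(i, 0); py[i] = points(i, 1); pz[i] = points(i, 2);
  }
  std::vector<Tet> tets = delaunay(px, py, pz);
  int m = (int)tets.size();
  if (m == 0) stop("no tetrahedra (degenerate point set)");

  // recompute circumradii from the final vertices (exact, not incremental)
  std::vector<double> rad(m), vol(m);
  for (int t = 0; t < m; ++t) {
    double cx, cy, cz, r2;
    if (circumsphere(px, py, pz, tets[t].v, cx, cy, cz, r2))
      rad[t] = std::sqrt(r2);
    else
      rad[t] = 1e150;
    vol[t] = tet_volume(px, py, pz, tets[t].v);
  }

  // face -> incident tets (1 or 2)
  typedef std::array<int, 3> Face;
  std::map<Face, std::pair<int, int> > inc;
  static const int fi[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
  for (int t = 0; t < m; ++t) {
    for (int f = 0; f < 4; ++f) {
      Face fa = {tets[t].v[fi[f][0]], tets[t].v[fi[f][1]],
                 tets[t].v[fi[f][2]]};
      std::sort(fa.begin(), fa.end());
      std::map<Face, std::pair<int, int> >::iterator it = inc.find(fa);
      if (it == inc.end()) inc[fa] = std::make_pair(t, -1);
      else it->second.second = t;
    }
  }

  std::vector<int> order(m);
  for (int t = 0; t < m; ++t) order[t] = t;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return rad[a] < rad[b]; });

  UnionFind uf(m);
  std::vector<bool> added(m, false);
  std::vector<int> cover(n, 0);
  int covered = 0, components = 0;
  double alpha = rad[order[m - 1]];
  bool done = false;
  for (int k = 0; k < m && !done; ++k) {
    int t = order[k];
    added[t] = true;
    ++components;
    for (int j = 0; j < 4; ++j)
      if (cover[tets[t].v[j]]++ == 0) ++covered;
    for (int f = 0; f < 4; ++f) {
      Face fa = {tets[t].v[fi[f][0]], tets[t].v[fi[f][1]],
                 tets[t].v[fi[f][2]]};
      std::sort(fa.begin(), fa.end());
      std::pair<int, int> pr = inc[fa];
      int other = (pr.first == t) ? pr.second : pr.first;
      if (other >= 0 && added[other] && uf.unite(t, other)) --components;
    }
    bool tie_ahead = (k + 1 < m) &&
        (rad[order[k + 1]] <= rad[t] * (1.0 + 1e-12));
    if (!tie_ahead && covered == n && components == 1) {
      alpha = rad[t];
      done = true;
    }
  }

  double alpha_used = alpha * scale;
  double total_vol = 0.0, total_area = 0.0;
  std::vector<bool> in_complex(m, false);
  for (int t = 0; t < m; ++t)
    if (rad[t] <= alpha_used * (1.0 + 1e-9)) in_complex[t] = true;
  for (int t = 0; t < m; ++t) if (in_complex[t]) total_vol += vol[t];
  for (std::map<Face, std::pair<int, int> >::iterator it = inc.begin();
       it != inc.end(); ++it) {
    int a = it->second.first, b = it->second.second;
    bool ina = in_complex[a];
    bool inb = (b >= 0) && in_complex[b];
    if (ina != inb)
      total_area += tri_area(px, py, pz, it->first[0], it->first[1],
                             it->first[2]);
  }
  return List::create(_["volume"] = total_vol, _["area"] = total_area,
                      _["alpha"] = alpha_used, _["critical_alpha"] = alpha,
                      _["n_tets"] = m);
}
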