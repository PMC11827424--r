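#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Incremental Bowyer-Watson Delaunay triangulation.
// Input points must be free of exact duplicates (deduplicated in R).
// Returns 1-based vertex index triples plus squared circumradii.

struct Tri {
  int a, b, c;
  double cx, cy, r2;  // circumcircle
  bool alive;
};

static inline void circumcircle(double ax, double ay, double bx, double by,
                                double cx_, double cy_, Tri &t) {
  double d = 2.0 * (ax * (by - cy_) + bx * (cy_ - ay) + cx_ * (ay - by));
  if (std::fabs(d) < 1e-300) {
    // degenerate (collinear): infinite circumcircle, will absorb any point
    t.cx = 0.0; t.cy = 0.0; t.r2 = R_PosInf;
    return;
  }
  double a2 = ax * ax + ay * ay;
  double b2 = bx * bx + by * by;
  double c2 = cx_ * cx_ + cy_ * cy_;
  t.cx = (a2 * (by - cy_) + b2 * (cy_ - ay) + c2 * (ay - by)) / d;
  t.cy = (a2 * (cx_ - bx) + b2 * (ax - cx_) + c2 * (bx - ax)) / d;
  double dx = ax - t.cx, dy = ay - t.cy;
  t.r2 = dx * dx + dy * dy;
}

// [[Rcpp::export]]
List cpp_delaunay(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) return List::create(_["tri"] = IntegerMatrix(0, 3),
                                 _["r2"] = NumericVector(0));

  // super-triangle comfortably enclosing all points
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) dmax = 1.0;
  double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
  double M = 64.0 * dmax;

  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) { px[i] = x[i]; py[i] = y[i]; }
  px[n] = midx - 2.0 * M; py[n] = midy - M;
  px[n + 1] = midx + 2.0 * M; py[n + 1] = midy - M;
  px[n + 2] = midx; py[n + 2] = midy + 2.0 * M;

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  Tri super; super.a = n; super.b = n + 1; super.c = n + 2; super.alive = true;
  circumcircle(px[n], py[n], px[n + 1], py[n + 1], px[n + 2], py[n + 2], super);
  tris.push_back(super);

  std::vector<int> bad;
  // edge -> count within the cavity; key packs the two vertex ids
  std::unordered_map<int64_t, std::pair<int, int>> edges;
  double tol = 1e-9 * dmax * dmax;

  for (int p = 0; p < n; ++p) {
    bad.clear();
    edges.clear();
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double dx = px[p] - tris[t].cx, dy = py[p] - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2 + tol) bad.push_back(t);
    }
    for (int bi : bad) {
      int vs[3] = {tris[bi].a, tris[bi].b, tris[bi].c};
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e + 1) % 3];
        int lo = std::min(u, v), hi = std::max(u, v);
        int64_t key = (int64_t)lo * (int64_t)(n + 3) + hi;
        auto it = edges.find(key);
        if (it == edges.end()) edges[key] = std::make_pair(u, v);
        else it->second.first = -1;  // shared edge: interior of cavity
      }
      tris[bi].alive = false;
    }
    for (auto &kv : edges) {
      if (kv.second.first < 0) continue;  // interior edge
      int64_t key = kv.first;
      int lo = (int)(key / (n + 3)), hi = (int)(key % (n + 3));
      Tri nt; nt.a = lo; nt.b = hi; nt.c = p; nt.alive = true;
      circumcircle(px[lo], py[lo], px[hi], py[hi], px[p], py[p], nt);
      tris.push_back(nt);
    }
  }

  int keep = 0;
  for (auto &t : tris)
    if (t.alive && t.a < n && t.b < n && t.c < n) ++keep;
  IntegerMatrix out(keep, 3);
  NumericVector r2(keep);
  int k = 0;
  for (auto &t : tris) {
    if (!(t.alive && t.a < n && t.b < n && t.c < n)) continue;
    out(k, 0) = t.a + 1; out(k, 1) = t.b + 1; out(k, 2) = t.c + 1;
    r2[k] = t.r2;
    ++k;
  }
  return List::create(_["tri"] = out, _["r2"] = r2);
}

// All unordered point pairs (i < j, 1-based) within distance eps,
// found by hashing points onto an eps-sized grid.
// [[Rcpp::export]]
List cpp_radius_pairs(NumericVector x, NumericVector y, double eps) {
  int n = x.size();
  double e2 = eps * eps;
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(n * 2);
  std::vector<int64_t> gx(n), gy(n);
  for (int i = 0; i < n; ++i) {
    gx[i] = (int64_t)std::floor(x[i] / eps);
    gy[i] = (int64_t)std::floor(y[i] / eps);
    grid[(gx[i] << 32) ^ (gy[i] & 0xffffffffLL)].push_back(i);
  }
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    for (int64_t dx = -1; dx <= 1; ++dx) {
      for (int64_t dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(((gx[i] + dx) << 32) ^ ((gy[i] + dy) & 0xffffffffLL));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= e2) { ii.push_back(i + 1); jj.push_back(j + 1); }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj));
}

// For each query point, whether it lies in (or on the edge of) any of the
// supplied triangles. Triangle t has vertices (tx[t,0..2], ty[t,0..2]).
// [[Rcpp::export]]
LogicalVector cpp_points_in_tris(NumericVector px, NumericVector py,
                                 NumericMatrix tx, NumericMatrix ty) {
  int np = px.size(), nt = tx.nrow();
  LogicalVector out(np);
  std::vector<double> bx0(nt), bx1(nt), by0(nt), by1(nt);
  double scale = 1.0;
  for (int t = 0; t < nt; ++t) {
    bx0[t] = std::min({tx(t, 0), tx(t, 1), tx(t, 2)});
    bx1[t] = std::max({tx(t, 0), tx(t, 1), tx(t, 2)});
    by0[t] = std::min({ty(t, 0), ty(t, 1), ty(t, 2)});
    by1[t] = std::max({ty(t, 0), ty(t, 1), ty(t, 2)});
    scale = std::max(scale, std::max(bx1[t] - bx0[t], by1[t] - by0[t]));
  }
  double tol = 1e-9 * scale * scale;
  for (int i = 0; i < np; ++i) {
    double X = px[i], Y = py[i];
    bool inside = false;
    for (int t = 0; t < nt && !inside; ++t) {
      if (X < bx0[t] - 1e-9 || X > bx1[t] + 1e-9 ||
          Y < by0[t] - 1e-9 || Y > by1[t] + 1e-9) continue;
      double ax = tx(t, 0), ay = ty(t, 0);
      double bx = tx(t, 1), by = ty(t, 1);
      double cx = tx(t, 2), cy = ty(t, 2);
      double d1 = (bx - ax) * (Y - ay) - (by - ay) * (X - ax);
      double d2 = (cx - bx) * (Y - by) - (cy - by) * (X - bx);
      double d3 = (ax - cx) * (Y - cy) - (ay - cy) * (X - cx);
      bool has_neg = (d1 < -tol) || (d2 < -tol) || (d3 < -tol);
      bool has_pos = (d1 > tol) || (d2 > tol) || (d3 > tol);
      if (!(has_neg && has_pos)) inside = true;
    }
    out[i] = inside;
  }
  return out;
}
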