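#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- small 2D polygon helpers (Sutherland-Hodgman clipping) ----

struct P2 { double u, v; };

// clip convex polygon by half-plane a*u + b*v <= g
static void clip_halfplane(std::vector<P2> &poly, double a, double b, double g) {
  if (poly.empty()) return;
  std::vector<P2> out;
  out.reserve(poly.size() + 2);
  size_t n = poly.size();
  for (size_t t = 0; t < n; ++t) {
    const P2 &p = poly[t];
    const P2 &q = poly[(t + 1) % n];
    double fp = a * p.u + b * p.v - g;
    double fq = a * q.u + b * q.v - g;
    bool pin = fp <= 0.0, qin = fq <= 0.0;
    if (pin) out.push_back(p);
    if (pin != qin) {
      double s = fp / (fp - fq);
      P2 x;
      x.u = p.u + s * (q.u - p.u);
      x.v = p.v + s * (q.v - p.v);
      out.push_back(x);
    }
  }
  poly.swap(out);
}

static double poly_area(const std::vector<P2> &poly) {
  double a = 0.0;
  size_t n = poly.size();
  if (n < 3) return 0.0;
  for (size_t t = 0; t < n; ++t) {
    const P2 &p = poly[t];
    const P2 &q = poly[(t + 1) % n];
    a += p.u * q.v - q.u * p.v;
  }
  return std::fabs(a) * 0.5;
}

// Voronoi-facet test: atoms i and j share a Voronoi facet iff the set of
// sphere centers equidistant from i and j and strictly closer to them than to
// every other atom has positive 2D measure on the bisector plane. Each other
// atom k forbids an open half-plane there; the facet survives iff the clipped
// region keeps positive area.
static bool voronoi_facet(const NumericMatrix &pts, int i, int j,
                          double box, double areatol) {
  double nx = pts(j, 0) - pts(i, 0);
  double ny = pts(j, 1) - pts(i, 1);
  double nz = pts(j, 2) - pts(i, 2);
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (nn < 1e-12) return false;
  nx /= nn; ny /= nn; nz /= nn;
  // orthonormal basis of the bisector plane
  double ax = 1.0, ay = 0.0, az = 0.0;
  if (std::fabs(nx) > 0.9) { ax = 0.0; ay = 1.0; }
  double e1x = ny * az - nz * ay, e1y = nz * ax - nx * az, e1z = nx * ay - ny * ax;
  double e1n = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
  e1x /= e1n; e1y /= e1n; e1z /= e1n;
  double e2x = ny * e1z - nz * e1y, e2y = nz * e1x - nx * e1z, e2z = nx * e1y - ny * e1x;
  double c0x = 0.5 * (pts(i, 0) + pts(j, 0));
  double c0y = 0.5 * (pts(i, 1) + pts(j, 1));
  double c0z = 0.5 * (pts(i, 2) + pts(j, 2));
  double qix = pts(i, 0) - c0x, qiy = pts(i, 1) - c0y, qiz = pts(i, 2) - c0z;
  double qi2 = qix * qix + qiy * qiy + qiz * qiz;

  std::vector<P2> poly(4);
  poly[0].u = -box; poly[0].v = -box;
  poly[1].u =  box; poly[1].v = -box;
  poly[2].u =  box; poly[2].v =  box;
  poly[3].u = -box; poly[3].v =  box;

  int n = pts.nrow();
  for (int k = 0; k < n; ++k) {
    if (k == i || k == j) continue;
    double qkx = pts(k, 0) - c0x, qky = pts(k, 1) - c0y, qkz = pts(k, 2) - c0z;
    double dx = qkx - qix, dy = qky - qiy, dz = qkz - qiz;
    double a = 2.0 * (e1x * dx + e1y * dy + e1z * dz);
    double b = 2.0 * (e2x * dx + e2y * dy + e2z * dz);
    double g = (qkx * qkx + qky * qky + qkz * qkz) - qi2;
    if (std::fabs(a) < 1e-14 && std::fabs(b) < 1e-14) {
      if (g <= 0.0) return false;  // k dominates the whole plane
      continue;
    }
    clip_halfplane(poly, a, b, g);
    if (poly.size() < 3) return false;
  }
  return poly_area(poly) > areatol;
}

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay_edges(NumericMatrix pts, double box = 1e7,
                                 double areatol = 1e-8) {
  int n = pts.nrow();
  std::vector<int> ei, ej;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (voronoi_facet(pts, i, j, box, areatol)) {
        ei.push_back(i + 1);
        ej.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t t = 0; t < ei.size(); ++t) {
    out(t, 0) = ei[t];
    out(t, 1) = ej[t];
  }
  return out;
}

// ---- beta-skeleton angle filter ----

// keep edge (i,j) iff no other point k subtends an angle >= beta_deg at k.
// Points with angle >= theta (theta <= 90) lie within d/sin(theta) of both
// endpoints, which bounds the scan.
// [[Rcpp::export]]
LogicalVector cpp_beta_keep(NumericMatrix pts, IntegerMatrix edges,
                            double beta_deg) {
  int m = edges.nrow(), n = pts.nrow();
  double theta = beta_deg * M_PI / 180.0;
  double cth = std::cos(theta);
  double sth = std::sin(theta);
  LogicalVector keep(m);
  for (int t = 0; t < m; ++t) {
    int i = edges(t, 0) - 1, j = edges(t, 1) - 1;
    double dx = pts(j, 0) - pts(i, 0);
    double dy = pts(j, 1) - pts(i, 1);
    double dz = pts(j, 2) - pts(i, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double bound = (sth > 1e-9) ? d / sth : R_PosInf;
    double bound2 = bound * bound;
    bool ok = true;
    for (int k = 0; k < n && ok; ++k) {
      if (k == i || k == j) continue;
      double ax = pts(i, 0) - pts(k, 0);
      double ay = pts(i, 1) - pts(k, 1);
      double az = pts(i, 2) - pts(k, 2);
      double a2 = ax * ax + ay * ay + az * az;
      if (a2 > bound2) continue;
      double bx = pts(j, 0) - pts(k, 0);
      double by = pts(j, 1) - pts(k, 1);
      double bz = pts(j, 2) - pts(k, 2);
      double b2 = bx * bx + by * by + bz * bz;
      if (b2 > bound2) continue;
      if (a2 < 1e-20 || b2 < 1e-20) { ok = false; break; }  // coincident point
      double cosk = (ax * bx + ay * by + az * bz) / std::sqrt(a2 * b2);
      if (cosk <= cth) ok = false;  // angle at k >= beta: strict rejection
    }
    keep[t] = ok;
  }
  return keep;
}

// ---- Shrake-Rupley solvent accessible surface area ----

// [[Rcpp::export]]
NumericVector cpp_shrake_rupley(NumericMatrix pts, NumericVector radii,
                                double probe = 1.4, int npts = 960) {
  int n = pts.nrow();
  // deterministic Fibonacci-spiral sphere points
  std::vector<double> sx(npts), sy(npts), sz(npts);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));  // golden angle
  for (int t = 0; t < npts; ++t) {
    double z = 1.0 - 2.0 * (t + 0.5) / npts;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * t;
    sx[t] = r * std::cos(phi);
    sy[t] = r * std::sin(phi);
    sz[t] = z;
  }
  NumericVector asa(n);
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    double Ri = radii[i] + probe;
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double Rj = radii[j] + probe;
      double dx = pts(j, 0) - pts(i, 0);
      double dy = pts(j, 1) - pts(i, 1);
      double dz = pts(j, 2) - pts(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double rr = Ri + Rj;
      if (d2 < rr * rr) nbr.push_back(j);
    }
    int acc = 0;
    for (int t = 0; t < npts; ++t) {
      double px = pts(i, 0) + Ri * sx[t];
      double py = pts(i, 1) + Ri * sy[t];
      double pz = pts(i, 2) + Ri * sz[t];
      bool free_pt = true;
      for (size_t u = 0; u < nbr.size(); ++u) {
        int j = nbr[u];
        double Rj = radii[j] + probe;
        double dx = px - pts(j, 0);
        double dy = py - pts(j, 1);
        double dz = pz - pts(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    asa[i] = 4.0 * M_PI * Ri * Ri * ((double)acc / npts);
  }
  return asa;
}
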