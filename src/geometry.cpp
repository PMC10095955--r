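// Geometry core for the polygonal tissue simulator: convex half-plane
// clipping, power-diagram (Laguerre) cells with area-targeted weight
// fitting, area-exact chord splits, shared-edge detection, scanline
// rasterization, and grayscale morphological reconstruction by erosion.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::vector<double> vd;

// clip convex polygon (ccw) by half-plane a*x + b*y <= c (Sutherland-Hodgman)
static void clip_hp(vd &xs, vd &ys, double a, double b, double c) {
  size_t n = xs.size();
  if (n < 3) { xs.clear(); ys.clear(); return; }
  vd nx, ny;
  nx.reserve(n + 4); ny.reserve(n + 4);
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    double di = a * xs[i] + b * ys[i] - c;
    double dj = a * xs[j] + b * ys[j] - c;
    if (di <= 0.0) { nx.push_back(xs[i]); ny.push_back(ys[i]); }
    if ((di < 0.0 && dj > 0.0) || (di > 0.0 && dj < 0.0)) {
      double t = di / (di - dj);
      nx.push_back(xs[i] + t * (xs[j] - xs[i]));
      ny.push_back(ys[i] + t * (ys[j] - ys[i]));
    }
  }
  xs.swap(nx); ys.swap(ny);
  if (xs.size() < 3) { xs.clear(); ys.clear(); }
}

static double parea(const vd &xs, const vd &ys) {
  double s = 0.0;
  size_t n = xs.size();
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    s += xs[i] * ys[j] - xs[j] * ys[i];
  }
  return 0.5 * s;
}

static void poly_from_matrix(const NumericMatrix &m, vd &xs, vd &ys) {
  int n = m.nrow();
  xs.assign(n, 0.0); ys.assign(n, 0.0);
  for (int i = 0; i < n; ++i) { xs[i] = m(i, 0); ys[i] = m(i, 1); }
}

static NumericMatrix poly_to_matrix(const vd &xs, const vd &ys) {
  int n = xs.size();
  NumericMatrix m(n, 2);
  for (int i = 0; i < n; ++i) { m(i, 0) = xs[i]; m(i, 1) = ys[i]; }
  return m;
}

// power-diagram cell of site i: domain clipped by all radical axes
static void power_cell(int i, const NumericMatrix &pts, const NumericVector &w,
                       const vd &dx, const vd &dy, vd &xs, vd &ys) {
  xs = dx; ys = dy;
  int n = pts.nrow();
  double xi = pts(i, 0), yi = pts(i, 1);
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double xj = pts(j, 0), yj = pts(j, 1);
    double a = 2.0 * (xj - xi);
    double b = 2.0 * (yj - yi);
    double c = xj * xj + yj * yj - xi * xi - yi * yi + w[i] - w[j];
    clip_hp(xs, ys, a, b, c);
    if (xs.empty()) return;
  }
}

// [[Rcpp::export]]
List cpp_power_cells(NumericMatrix pts, NumericVector w, NumericMatrix domain) {
  int n = pts.nrow();
  vd dx, dy, xs, ys;
  poly_from_matrix(domain, dx, dy);
  List out(n);
  for (int i = 0; i < n; ++i) {
    power_cell(i, pts, w, dx, dy, xs, ys);
    out[i] = poly_to_matrix(xs, ys);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_power_areas(NumericMatrix pts, NumericVector w, NumericMatrix domain) {
  int n = pts.nrow();
  vd dx, dy, xs, ys;
  poly_from_matrix(domain, dx, dy);
  NumericVector areas(n);
  for (int i = 0; i < n; ++i) {
    power_cell(i, pts, w, dx, dy, xs, ys);
    areas[i] = xs.empty() ? 0.0 : parea(xs, ys);
  }
  return areas;
}

// fixed-point fit of power weights so cell areas match targets;
// dA_i/dw_i is O(1) for isotropic tilings, so a damped Jacobi update works
// [[Rcpp::export]]
List cpp_fit_power_weights(NumericMatrix pts0, NumericVector targets,
                           NumericMatrix domain, NumericVector w0,
                           double tol, int maxit, double damp) {
  int n = pts0.nrow();
  vd dx, dy, xs, ys;
  poly_from_matrix(domain, dx, dy);
  NumericMatrix pts = clone(pts0), best_pts = clone(pts0);
  NumericVector w = clone(w0), best_w = clone(w0);
  NumericVector areas(n);
  double best_err = R_PosInf;
  double d = damp;
  int stagnant = 0, it = 0;
  for (it = 0; it < maxit; ++it) {
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      power_cell(i, pts, w, dx, dy, xs, ys);
      areas[i] = xs.empty() ? 0.0 : parea(xs, ys);
      double e = std::fabs(areas[i] - targets[i]) / targets[i];
      if (e > err) err = e;
    }
    if (err < best_err) {
      if (err < best_err * 0.995) stagnant = 0; else ++stagnant;
      best_err = err; best_w = clone(w); best_pts = clone(pts);
    } else {
      ++stagnant;
    }
    if (err < tol) break;
    // stagnation guard: restart from the best state with a gentle Lloyd
    // relocation (generators move towards their cell centroids), slower
    if (stagnant >= 25) {
      d *= 0.7;
      w = clone(best_w);
      pts = clone(best_pts);
      for (int i = 0; i < n; ++i) {
        power_cell(i, pts, w, dx, dy, xs, ys);
        if (xs.empty()) continue;
        // polygon centroid
        double cx = 0, cy = 0, aa = 0;
        size_t m = xs.size();
        for (size_t k = 0; k < m; ++k) {
          size_t k2 = (k + 1) % m;
          double cr = xs[k] * ys[k2] - xs[k2] * ys[k];
          cx += (xs[k] + xs[k2]) * cr;
          cy += (ys[k] + ys[k2]) * cr;
          aa += cr;
        }
        if (std::fabs(aa) > 1e-12) {
          cx /= 3.0 * aa; cy /= 3.0 * aa;
          pts(i, 0) += 0.5 * (cx - pts(i, 0));
          pts(i, 1) += 0.5 * (cy - pts(i, 1));
        }
      }
      stagnant = 0;
      if (d < 1e-3) break;
      continue;
    }
    double mw = 0.0;
    for (int i = 0; i < n; ++i) {
      // dA/dw ~ pi/2 for roundish cells
      w[i] += d * (targets[i] - areas[i]) / 1.5708;
      mw += w[i];
    }
    mw /= n;
    for (int i = 0; i < n; ++i) w[i] -= mw;
  }
  // recompute areas at the best state
  for (int i = 0; i < n; ++i) {
    power_cell(i, best_pts, best_w, dx, dy, xs, ys);
    areas[i] = xs.empty() ? 0.0 : parea(xs, ys);
  }
  return List::create(_["w"] = best_w, _["pts"] = best_pts,
                      _["areas"] = areas, _["iterations"] = it,
                      _["max_rel_err"] = best_err);
}

// split convex polygon by a chord with direction (ux,uy) such that the
// daughter containing/nearest ref gets fraction `frac` of the area
// [[Rcpp::export]]
List cpp_split_polygon_frac(NumericMatrix poly, double ux, double uy,
                            double frac, double refx, double refy) {
  vd px, py;
  poly_from_matrix(poly, px, py);
  double A = parea(px, py);
  if (A <= 0 || px.size() < 3) stop("degenerate polygon");
  double nl = std::sqrt(ux * ux + uy * uy);
  if (nl <= 0) stop("zero chord direction");
  // normal to the chord
  double nx = -uy / nl, ny = ux / nl;
  double lo = R_PosInf, hi = R_NegInf;
  for (size_t i = 0; i < px.size(); ++i) {
    double t = nx * px[i] + ny * py[i];
    if (t < lo) lo = t;
    if (t > hi) hi = t;
  }
  double tref = nx * refx + ny * refy;
  // area of the {n.x <= c} side as a function of c is increasing
  // find c so that low side has fraction f
  auto area_low = [&](double c) {
    vd xs = px, ys = py;
    clip_hp(xs, ys, nx, ny, c);
    return xs.empty() ? 0.0 : parea(xs, ys);
  };
  auto solve_c = [&](double f) {
    double a = lo, b = hi;
    for (int k = 0; k < 70; ++k) {
      double m = 0.5 * (a + b);
      if (area_low(m) < f * A) a = m; else b = m;
    }
    return 0.5 * (a + b);
  };
  // try ref on the low side first
  double c = solve_c(frac);
  bool ref_low = (tref <= c);
  if (!ref_low) {
    double c2 = solve_c(1.0 - frac);
    if (tref >= c2) {
      c = c2;
      ref_low = false;
    } else {
      // ref sits between the two candidate chords; give it the nearer side
      if (std::fabs(tref - c) <= std::fabs(tref - c2)) ref_low = true;
      else { c = c2; ref_low = false; }
    }
  }
  vd lx = px, ly = py, hx = px, hy = py;
  clip_hp(lx, ly, nx, ny, c);
  clip_hp(hx, hy, -nx, -ny, -c);
  if (lx.empty() || hx.empty()) stop("geometry error: chord fails to split polygon");
  NumericMatrix mlow = poly_to_matrix(lx, ly), mhigh = poly_to_matrix(hx, hy);
  if (ref_low) return List::create(_["ref_side"] = mlow, _["other"] = mhigh);
  return List::create(_["ref_side"] = mhigh, _["other"] = mlow);
}

// total shared boundary length between two convex polygons (collinear
// overlapping edge segments within tol)
// [[Rcpp::export]]
double cpp_shared_edge_length(NumericMatrix A, NumericMatrix B, double tol) {
  vd ax, ay, bx, by;
  poly_from_matrix(A, ax, ay);
  poly_from_matrix(B, bx, by);
  size_t na = ax.size(), nb = bx.size();
  double total = 0.0;
  for (size_t i = 0; i < na; ++i) {
    size_t i2 = (i + 1) % na;
    double ux = ax[i2] - ax[i], uy = ay[i2] - ay[i];
    double L = std::sqrt(ux * ux + uy * uy);
    if (L < tol) continue;
    ux /= L; uy /= L;
    double best = 0.0;
    for (size_t j = 0; j < nb; ++j) {
      size_t j2 = (j + 1) % nb;
      // distances of B edge endpoints from the A edge line
      double d1 = std::fabs((bx[j] - ax[i]) * uy - (by[j] - ay[i]) * ux);
      double d2 = std::fabs((bx[j2] - ax[i]) * uy - (by[j2] - ay[i]) * ux);
      if (d1 > tol || d2 > tol) continue;
      double t1 = (bx[j] - ax[i]) * ux + (by[j] - ay[i]) * uy;
      double t2 = (bx[j2] - ax[i]) * ux + (by[j2] - ay[i]) * uy;
      double qlo = std::min(t1, t2), qhi = std::max(t1, t2);
      double ov = std::min(qhi, L) - std::max(qlo, 0.0);
      if (ov > best) best = ov;
    }
    total += best;
  }
  return total;
}

// scanline-rasterize convex polygons into an integer label image (H x W);
// pixel (r, c) centre is at x = ox + (c - 0.5) px, y = oy + (H - r + 0.5) px
// (row 1 = top of the frame); later polygons overwrite earlier ones on
// shared-boundary pixels, which keeps ties deterministic
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize(List polys, IntegerVector ids, int W, int H,
                            double px, double ox, double oy) {
  IntegerMatrix lab(H, W);
  int np = polys.size();
  for (int k = 0; k < np; ++k) {
    NumericMatrix P = polys[k];
    int n = P.nrow();
    if (n < 3) continue;
    double ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (P(i, 1) < ymin) ymin = P(i, 1);
      if (P(i, 1) > ymax) ymax = P(i, 1);
    }
    int r0 = (int)std::floor(H - (ymax - oy) / px + 0.5) - 1;
    int r1 = (int)std::ceil(H - (ymin - oy) / px + 0.5) + 1;
    if (r0 < 1) r0 = 1;
    if (r1 > H) r1 = H;
    for (int r = r0; r <= r1; ++r) {
      double y = oy + (H - r + 0.5) * px;
      double xlo = R_PosInf, xhi = R_NegInf;
      bool any = false;
      for (int i = 0; i < n; ++i) {
        int j = (i + 1) % n;
        double yi = P(i, 1), yj = P(j, 1);
        if ((yi <= y) == (yj <= y)) continue;
        double x = P(i, 0) + (y - yi) / (yj - yi) * (P(j, 0) - P(i, 0));
        if (x < xlo) xlo = x;
        if (x > xhi) xhi = x;
        any = true;
      }
      if (!any) continue;
      int c0 = (int)std::ceil((xlo - ox) / px + 0.5 - 1e-9);
      int c1 = (int)std::floor((xhi - ox) / px + 0.5 + 1e-9);
      if (c0 < 1) c0 = 1;
      if (c1 > W) c1 = W;
      for (int c = c0; c <= c1; ++c) lab(r - 1, c - 1) = ids[k];
    }
  }
  return lab;
}

// grayscale morphological reconstruction by erosion of `marker` above
// `floor_img` (marker >= floor), 8-connected, by alternating raster sweeps
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_erosion(NumericMatrix marker, NumericMatrix floor_img,
                                      int max_pass = 200) {
  int H = marker.nrow(), W = marker.ncol();
  NumericMatrix rec(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      rec(r, c) = std::max(marker(r, c), floor_img(r, c));
  for (int pass = 0; pass < max_pass; ++pass) {
    bool changed = false;
    // forward sweep
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        double v = rec(r, c);
        if (r > 0) v = std::min(v, rec(r - 1, c));
        if (c > 0) v = std::min(v, rec(r, c - 1));
        if (r > 0 && c > 0) v = std::min(v, rec(r - 1, c - 1));
        if (r < H - 1 && c > 0) v = std::min(v, rec(r + 1, c - 1));
        v = std::max(v, floor_img(r, c));
        if (v < rec(r, c)) { rec(r, c) = v; changed = true; }
      }
    }
    // backward sweep
    for (int c = W - 1; c >= 0; --c) {
      for (int r = H - 1; r >= 0; --r) {
        double v = rec(r, c);
        if (r < H - 1) v = std::min(v, rec(r + 1, c));
        if (c < W - 1) v = std::min(v, rec(r, c + 1));
        if (r < H - 1 && c < W - 1) v = std::min(v, rec(r + 1, c + 1));
        if (r > 0 && c < W - 1) v = std::min(v, rec(r - 1, c + 1));
        v = std::max(v, floor_img(r, c));
        if (v < rec(r, c)) { rec(r, c) = v; changed = true; }
      }
    }
    if (!changed) break;
  }
  return rec;
}
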