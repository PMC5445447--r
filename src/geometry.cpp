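#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Connected components (8-connectivity) -------------------------------------
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix label_blobs_cpp(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next_label = 0;
  std::queue<std::pair<int,int> > q;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next_label;
      lab(y, x) = next_label;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        int cy = q.front().first, cx = q.front().second; q.pop();
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dy == 0 && dx == 0) continue;
            int ny = cy + dy, nx = cx + dx;
            if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
            if (mask(ny, nx) && lab(ny, nx) == 0) {
              lab(ny, nx) = next_label;
              q.push(std::make_pair(ny, nx));
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Moore boundary tracing -----------------------------------------------------
// ---------------------------------------------------------------------------

// Clockwise (on screen, y down) Moore neighbourhood starting at W.
static const int NBX[8] = {-1, -1,  0,  1, 1, 1, 0, -1};
static const int NBY[8] = { 0, -1, -1, -1, 0, 1, 1,  1};

// Trace the outer boundary of the component with the given label.
// Returns an m x 2 matrix of (x, y) pixel coordinates, 1-based, closed chain
// (last point != first point; closure implicit).
// [[Rcpp::export]]
NumericMatrix trace_boundary_cpp(const IntegerMatrix& lab, int label) {
  const int H = lab.nrow(), W = lab.ncol();
  int sx = -1, sy = -1;
  for (int y = 0; y < H && sx < 0; ++y)
    for (int x = 0; x < W; ++x)
      if (lab(y, x) == label) { sx = x; sy = y; break; }
  if (sx < 0) stop("label not present in image");

  std::vector<int> bx, by;
  bx.push_back(sx); by.push_back(sy);

  // backtrack direction: we entered start from the west (scan order)
  int cx = sx, cy = sy;
  int dir_back = 0; // index into NB pointing at the backtrack pixel (W)
  int start_back = dir_back;
  const long maxit = 4L * (long)H * (long)W + 8;
  long it = 0;
  bool closed = false;
  while (++it < maxit) {
    // sweep clockwise starting just after the backtrack position
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (dir_back + k) % 8;
      int nx = cx + NBX[d], ny = cy + NBY[d];
      if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
      if (lab(ny, nx) == label) { found = d; break; }
    }
    if (found < 0) break; // isolated pixel
    int nx = cx + NBX[found], ny = cy + NBY[found];
    // new backtrack = direction from the new pixel to the previous neighbour
    // (the background pixel just before 'found' in the sweep, seen from new pixel)
    int prev = (found + 7) % 8;
    int px = cx + NBX[prev], py = cy + NBY[prev];
    int nb = 0;
    for (int d = 0; d < 8; ++d)
      if (nx + NBX[d] == px && ny + NBY[d] == py) { nb = d; break; }
    cx = nx; cy = ny; dir_back = nb;
    if (cx == sx && cy == sy && dir_back == start_back) { closed = true; break; }
    bx.push_back(cx); by.push_back(cy);
  }
  (void)closed;
  // drop a duplicated closing point if present
  int m = (int)bx.size();
  if (m > 1 && bx[m-1] == bx[0] && by[m-1] == by[0]) m -= 1;
  NumericMatrix out(m, 2);
  for (int i = 0; i < m; ++i) { out(i, 0) = bx[i] + 1.0; out(i, 1) = by[i] + 1.0; }
  return out;
}

// ---------------------------------------------------------------------------
// Polygon predicates ---------------------------------------------------------
// ---------------------------------------------------------------------------

static inline double orient(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static bool point_in_poly(double px, double py, const NumericMatrix& poly) {
  const int n = poly.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = poly(i, 0), yi = poly(i, 1);
    double xj = poly(j, 0), yj = poly(j, 1);
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector point_in_polygon_cpp(const NumericMatrix& pts,
                                   const NumericMatrix& poly) {
  const int m = pts.nrow();
  LogicalVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = point_in_poly(pts(i, 0), pts(i, 1), poly);
  return out;
}

// [[Rcpp::export]]
NumericVector dist_to_polygon_cpp(const NumericMatrix& pts,
                                  const NumericMatrix& poly) {
  const int m = pts.nrow(), n = poly.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    double best = std::numeric_limits<double>::infinity();
    for (int a = 0, b = n - 1; a < n; b = a++) {
      double x1 = poly(b, 0), y1 = poly(b, 1), x2 = poly(a, 0), y2 = poly(a, 1);
      double dx = x2 - x1, dy = y2 - y1;
      double L2 = dx * dx + dy * dy;
      double t = L2 > 0 ? ((px - x1) * dx + (py - y1) * dy) / L2 : 0.0;
      if (t < 0) t = 0; if (t > 1) t = 1;
      double qx = x1 + t * dx - px, qy = y1 + t * dy - py;
      double d = std::sqrt(qx * qx + qy * qy);
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Inner geometry: visibility graph + all-pairs shortest paths ---------------
// ---------------------------------------------------------------------------

// proper crossing of open segments (shared endpoints handled by the caller)
static bool segments_cross(double ax, double ay, double bx, double by,
                           double cx, double cy, double dx, double dy) {
  double o1 = orient(ax, ay, bx, by, cx, cy);
  double o2 = orient(ax, ay, bx, by, dx, dy);
  double o3 = orient(cx, cy, dx, dy, ax, ay);
  double o4 = orient(cx, cy, dx, dy, bx, by);
  return (o1 * o2 < 0) && (o3 * o4 < 0);
}

// [[Rcpp::export]]
bool is_simple_polygon_cpp(const NumericMatrix& poly) {
  const int n = poly.nrow();
  for (int a = 0; a < n; ++a) {
    int a2 = (a + 1) % n;
    for (int b = a + 1; b < n; ++b) {
      int b2 = (b + 1) % n;
      // skip edges sharing a vertex
      if (a == b || a2 == b || a == b2 || a2 == b2) continue;
      if (segments_cross(poly(a, 0), poly(a, 1), poly(a2, 0), poly(a2, 1),
                         poly(b, 0), poly(b, 1), poly(b2, 0), poly(b2, 1)))
        return false;
    }
  }
  return true;
}

// [[Rcpp::export]]
List inner_geometry_cpp(const NumericMatrix& poly) {
  const int n = poly.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix d(n, n);
  IntegerMatrix nxt(n, n);
  std::fill(d.begin(), d.end(), INF);
  std::fill(nxt.begin(), nxt.end(), 0);
  for (int i = 0; i < n; ++i) { d(i, i) = 0.0; nxt(i, i) = i + 1; }

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool adjacent = (j == i + 1) || (i == 0 && j == n - 1);
      bool visible = true;
      if (!adjacent) {
        for (int a = 0; a < n && visible; ++a) {
          int b = (a + 1) % n;
          if (a == i || a == j || b == i || b == j) continue;
          if (segments_cross(poly(i, 0), poly(i, 1), poly(j, 0), poly(j, 1),
                             poly(a, 0), poly(a, 1), poly(b, 0), poly(b, 1)))
            visible = false;
        }
        if (visible) {
          double mx = 0.5 * (poly(i, 0) + poly(j, 0));
          double my = 0.5 * (poly(i, 1) + poly(j, 1));
          if (!point_in_poly(mx, my, poly)) visible = false;
        }
      }
      if (visible) {
        double dx = poly(i, 0) - poly(j, 0), dy = poly(i, 1) - poly(j, 1);
        double w = std::sqrt(dx * dx + dy * dy);
        d(i, j) = w; d(j, i) = w;
        nxt(i, j) = j + 1; nxt(j, i) = i + 1;
      }
    }
  }

  // Floyd-Warshall with path reconstruction
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      if (d(i, k) == INF) continue;
      for (int j = 0; j < n; ++j) {
        double alt = d(i, k) + d(k, j);
        if (alt < d(i, j)) { d(i, j) = alt; nxt(i, j) = nxt(i, k); }
      }
    }

  return List::create(_["dist"] = d, _["next"] = nxt);
}

// ---------------------------------------------------------------------------
// Linear assignment (shortest augmenting path with potentials) --------------
// ---------------------------------------------------------------------------

// Returns for each row the assigned column (1-based); minimizes total cost.
// [[Rcpp::export]]
IntegerVector assignment_cpp(const NumericMatrix& cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<bool> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector perm(n);
  for (int j = 1; j <= n; ++j) perm[p[j] - 1] = j;
  return perm;
}

// ---------------------------------------------------------------------------
// Polygon rasterization (even-odd scanline at pixel centers) -----------------
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalMatrix fill_polygon_cpp(const NumericMatrix& poly, int nrow, int ncol) {
  LogicalMatrix out(nrow, ncol);
  const int n = poly.nrow();
  std::vector<double> xs;
  for (int y = 1; y <= nrow; ++y) {
    xs.clear();
    double fy = (double)y;
    for (int a = 0, b = n - 1; a < n; b = a++) {
      double y1 = poly(b, 1), y2 = poly(a, 1);
      if ((y1 > fy) == (y2 > fy)) continue; // half-open rule
      double x1 = poly(b, 0), x2 = poly(a, 0);
      xs.push_back(x1 + (fy - y1) * (x2 - x1) / (y2 - y1));
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int xa = (int)std::ceil(xs[k]);
      int xb = (int)std::floor(xs[k + 1]);
      if (xa < 1) xa = 1;
      if (xb > ncol) xb = ncol;
      for (int x = xa; x <= xb; ++x) out(y - 1, x - 1) = true;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bilinear sampling ----------------------------------------------------------
// ---------------------------------------------------------------------------

// img indexed [row = y, col = x], 1-based pixel centers; border-clamped.
// [[Rcpp::export]]
NumericVector bilinear_cpp(const NumericMatrix& img,
                           const NumericVector& x, const NumericVector& y) {
  const int H = img.nrow(), W = img.ncol();
  const int m = x.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double fx = x[i], fy = y[i];
    if (fx < 1) fx = 1; if (fx > W) fx = W;
    if (fy < 1) fy = 1; if (fy > H) fy = H;
    int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy);
    if (x0 >= W) x0 = W - 1;
    if (y0 >= H) y0 = H - 1;
    int x1 = x0 + 1, y1 = y0 + 1;
    double tx = fx - x0, ty = fy - y0;
    double v = (1 - tx) * (1 - ty) * img(y0 - 1, x0 - 1)
             + tx * (1 - ty) * img(y0 - 1, x1 - 1)
             + (1 - tx) * ty * img(y1 - 1, x0 - 1)
             + tx * ty * img(y1 - 1, x1 - 1);
    out[i] = v;
  }
  return out;
}
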