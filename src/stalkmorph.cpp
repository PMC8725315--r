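#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a logical matrix by iterative flood fill.
// connectivity: 4 or 8. Labels are assigned in raster (column-major) order of
// the first-seen pixel of each component, so labeling is deterministic.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % H, cc = idx / H;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * H);
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbor boundary tracing of a single-component mask with Jacob's
// stopping criterion. Returns ordered boundary pixel coordinates as 0-based
// (x, y) pairs (x = column, y = row), not explicitly closed. Out-of-image
// positions count as background, so components touching the border trace
// correctly.
// [[Rcpp::export]]
NumericMatrix moore_contour_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  // clockwise neighbor order starting at W: W NW N NE E SE S SW
  const int dr[] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[] = {-1, -1, 0, 1, 1, 1, 0, -1};
  int r0 = -1, c0 = -1;
  // topmost row, then leftmost column: scan rows first
  for (int r = 0; r < H && r0 < 0; ++r)
    for (int c = 0; c < W; ++c)
      if (mask(r, c)) { r0 = r; c0 = c; break; }
  if (r0 < 0) stop("mask has no foreground pixels");
  std::vector<int> xs, ys;
  xs.push_back(c0); ys.push_back(r0);
  int pr = r0, pc = c0;
  int bdir = 0;   // scan start: the W cell of the start pixel is background by scan order
  int d0 = -1;    // direction of the very first move (for Jacob's criterion)
  const long maxit = 8L * (long)H * (long)W + 16L;
  long it = 0;
  while (it++ < maxit) {
    int found = -1;
    for (int k = 0; k < 8; ++k) {
      int d = (bdir + k) % 8;
      int r2 = pr + dr[d], c2 = pc + dc[d];
      bool fg = (r2 >= 0 && r2 < H && c2 >= 0 && c2 < W) ? (bool)mask(r2, c2) : false;
      if (fg) { found = d; break; }
    }
    if (found < 0) break;  // isolated single pixel
    if (d0 < 0) {
      d0 = found;
    } else if (pr == r0 && pc == c0 && found == d0) {
      break;  // back at start about to repeat the first move: loop complete
    }
    pr += dr[found]; pc += dc[found];
    xs.push_back(pc); ys.push_back(pr);
    bdir = (found + 6) % 8;  // resume scan two steps back in clockwise order
  }
  // drop duplicated final start pixel if present
  int n = xs.size();
  if (n > 1 && xs[n - 1] == xs[0] && ys[n - 1] == ys[0]) n -= 1;
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  colnames(out) = CharacterVector::create("x", "y");
  return out;
}

// Minimum Euclidean distance from each query point to a closed polyline,
// measured against the segments (not only the vertices). poly rows are (x, y)
// vertices; the polyline is closed by joining the last vertex to the first.
// Returns distance and the coordinates of the nearest point on the polyline.
// [[Rcpp::export]]
NumericMatrix dist_to_polyline_cpp(NumericMatrix pts, NumericMatrix poly) {
  const int n = pts.nrow(), m = poly.nrow();
  if (m < 2) stop("polyline needs at least 2 vertices");
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    double best = R_PosInf, bx = poly(0, 0), by = poly(0, 1);
    for (int j = 0; j < m; ++j) {
      int k = (j + 1 == m) ? 0 : j + 1;
      double ax = poly(j, 0), ay = poly(j, 1);
      double ex = poly(k, 0) - ax, ey = poly(k, 1) - ay;
      double len2 = ex * ex + ey * ey;
      double t = 0.0;
      if (len2 > 0) {
        t = ((px - ax) * ex + (py - ay) * ey) / len2;
        if (t < 0) t = 0; else if (t > 1) t = 1;
      }
      double qx = ax + t * ex, qy = ay + t * ey;
      double dx = px - qx, dy = py - qy;
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bx = qx; by = qy; }
    }
    out(i, 0) = std::sqrt(best);
    out(i, 1) = bx;
    out(i, 2) = by;
  }
  colnames(out) = CharacterVector::create("dist", "x", "y");
  return out;
}
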