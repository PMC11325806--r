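#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Zhang-Suen thinning of a binary matrix (1 = foreground). Two sub-iterations
// per pass; repeats until a full pass deletes nothing.
// [[Rcpp::export]]
IntegerMatrix cpp_zhang_suen(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img = clone(mask);

  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c);
  };

  bool changed = true;
  std::vector<std::pair<int,int> > kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          int p2 = at(r-1, c),   p3 = at(r-1, c+1), p4 = at(r, c+1);
          int p5 = at(r+1, c+1), p6 = at(r+1, c),   p7 = at(r+1, c-1);
          int p8 = at(r, c-1),   p9 = at(r-1, c-1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int k = 0; k < 8; ++k) if (seq[k] == 0 && seq[k+1] == 1) ++A;
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k)
          img(kill[k].first, kill[k].second) = 0;
      }
    }
  }
  return img;
}

static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  // Felzenszwalb & Huttenlocher lower-envelope-of-parabolas pass.
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance from each pixel to the nearest zero
// (background) pixel. Returns squared distances; background pixels get 0.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  // finite sentinel keeps the parabola-intersection formula NaN-free on
  // all-foreground scan lines; any true distance beats it
  const double BIG = 1e12;
  NumericMatrix d2(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // column pass
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? BIG : 0.0;
    edt_1d(f, d, nr);
    for (int r = 0; r < nr; ++r) d2(r, c) = d[r];
  }
  // row pass
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d2(r, c);
    edt_1d(f, d, nc);
    for (int c = 0; c < nc; ++c) d2(r, c) = d[c];
  }
  return d2;
}

// Rasterize a constant-width stadium sweep of a polyline: pixel (r, c) of the
// output grid (offset by row0/col0, pixel centers at integer coordinates
// x = col, y = row) is foreground iff its center lies within halfwidth of the
// polyline (exact point-to-segment distance). Only pixels near each segment
// are visited.
// [[Rcpp::export]]
IntegerMatrix cpp_stadium_mask(NumericVector xs, NumericVector ys,
                               double halfwidth, int row0, int col0,
                               int nrows, int ncols) {
  int np = xs.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(static_cast<size_t>(nrows) * ncols, INF);
  double hw2 = halfwidth * halfwidth;
  int reach = (int)std::ceil(halfwidth) + 1;

  int nseg = (np == 1) ? 1 : np - 1;
  for (int s = 0; s < nseg; ++s) {
    double x1 = xs[s], y1 = ys[s];
    double x2 = (np == 1) ? x1 : xs[s + 1];
    double y2 = (np == 1) ? y1 : ys[s + 1];
    int rlo = (int)std::floor(std::min(y1, y2)) - reach - row0;
    int rhi = (int)std::ceil(std::max(y1, y2)) + reach - row0;
    int clo = (int)std::floor(std::min(x1, x2)) - reach - col0;
    int chi = (int)std::ceil(std::max(x1, x2)) + reach - col0;
    if (rlo < 0) rlo = 0;
    if (clo < 0) clo = 0;
    if (rhi >= nrows) rhi = nrows - 1;
    if (chi >= ncols) chi = ncols - 1;
    double dx = x2 - x1, dy = y2 - y1;
    double len2 = dx * dx + dy * dy;
    for (int r = rlo; r <= rhi; ++r) {
      double py = r + row0;
      for (int c = clo; c <= chi; ++c) {
        double px = c + col0;
        double t = 0.0;
        if (len2 > 0.0) {
          t = ((px - x1) * dx + (py - y1) * dy) / len2;
          if (t < 0.0) t = 0.0;
          if (t > 1.0) t = 1.0;
        }
        double ex = px - (x1 + t * dx), ey = py - (y1 + t * dy);
        double d2 = ex * ex + ey * ey;
        size_t idx = (size_t)c * nrows + r;
        if (d2 < dist[idx]) dist[idx] = d2;
      }
    }
  }
  IntegerMatrix out(nrows, ncols);
  for (int c = 0; c < ncols; ++c)
    for (int r = 0; r < nrows; ++r)
      out(r, c) = dist[(size_t)c * nrows + r] <= hw2 ? 1 : 0;
  return out;
}
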