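#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sum of the two directed mean nearest-point distances between equal- or
// unequal-length point sets (Euclidean mean distance).
// [[Rcpp::export]]
double cpp_emd(const NumericMatrix& A, const NumericMatrix& B) {
  const int na = A.nrow(), nb = B.nrow();
  double sab = 0.0, sba = 0.0;
  std::vector<double> minB(nb, R_PosInf);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1);
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1);
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
      if (d2 < minB[j]) minB[j] = d2;
    }
    sab += std::sqrt(best);
  }
  for (int j = 0; j < nb; ++j) sba += std::sqrt(minB[j]);
  return sab / na + sba / nb;
}

// Position-matched (pseudo-homologous) outline distance, equal counts:
// 2/n * sum_i |a_i - b_i|.
// [[Rcpp::export]]
double cpp_hed_equal(const NumericMatrix& A, const NumericMatrix& B) {
  const int n = A.nrow();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double dx = A(i, 0) - B(i, 0), dy = A(i, 1) - B(i, 1);
    s += std::sqrt(dx * dx + dy * dy);
  }
  return 2.0 * s / n;
}

// Even-odd scanline fill of the baseline-closed polygon onto a fixed grid.
// Marks cells whose center lies inside.
static void fill_mask(const NumericMatrix& P, double x0, double y0,
                      double cx, double cy, int nx, int ny,
                      std::vector<char>& mask) {
  const int n = P.nrow();
  std::vector<double> xs;
  for (int r = 0; r < ny; ++r) {
    const double yc = y0 + (r + 0.5) * cy;
    xs.clear();
    for (int e = 0; e < n; ++e) {
      const int f = (e + 1) % n;  // closing edge included
      const double y1 = P(e, 1), y2 = P(f, 1);
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        const double t = (yc - y1) / (y2 - y1);
        xs.push_back(P(e, 0) + t * (P(f, 0) - P(e, 0)));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c1 = (int)std::ceil((xs[k] - x0) / cx - 0.5);
      int c2 = (int)std::floor((xs[k + 1] - x0) / cx - 0.5);
      if (c1 < 0) c1 = 0;
      if (c2 >= nx) c2 = nx - 1;
      for (int c = c1; c <= c2; ++c) mask[(size_t)r * nx + c] = 1;
    }
  }
}

// Superimposed area overlap (similarity in [0,1]) on a fixed raster grid.
// [[Rcpp::export]]
double cpp_sao(const NumericMatrix& A, const NumericMatrix& B,
               double x0, double y0, double cx, double cy, int nx, int ny) {
  std::vector<char> ma((size_t)nx * ny, 0), mb((size_t)nx * ny, 0);
  fill_mask(A, x0, y0, cx, cy, nx, ny, ma);
  fill_mask(B, x0, y0, cx, cy, nx, ny, mb);
  long inter = 0, sa = 0, sb = 0;
  for (size_t k = 0; k < ma.size(); ++k) {
    sa += ma[k]; sb += mb[k];
    if (ma[k] && mb[k]) ++inter;
  }
  if (sa + sb == 0) return NA_REAL;
  return 2.0 * (double)inter / (double)(sa + sb);
}

// Exhaustive grid search over rotation x shift x scale for the transform of
// B (A fixed) minimizing a distance: 0 = EMD, 1 = HED, 2 = 1 - SAO.
// Returns (distance, rot, dx, dy, scale).
// [[Rcpp::export]]
NumericVector cpp_align_grid(const NumericMatrix& A, const NumericMatrix& B,
                             int measure,
                             const NumericVector& rots,
                             const NumericVector& dxs,
                             const NumericVector& dys,
                             const NumericVector& scales,
                             double x0, double y0, double cx, double cy,
                             int nx, int ny) {
  const int nb = B.nrow();
  NumericMatrix Bt(nb, 2);
  double best = R_PosInf, brot = 0, bdx = 0, bdy = 0, bsc = 1;
  // A is fixed across the whole search: rasterize it once for SAO
  std::vector<char> maskA;
  long cntA = 0;
  if (measure == 2) {
    maskA.assign((size_t)nx * ny, 0);
    fill_mask(A, x0, y0, cx, cy, nx, ny, maskA);
    for (size_t k = 0; k < maskA.size(); ++k) cntA += maskA[k];
  }
  for (int ir = 0; ir < rots.size(); ++ir) {
    const double co = std::cos(rots[ir]), si = std::sin(rots[ir]);
    for (int is = 0; is < scales.size(); ++is) {
      const double s = scales[is];
      for (int ix = 0; ix < dxs.size(); ++ix) {
        for (int iy = 0; iy < dys.size(); ++iy) {
          for (int p = 0; p < nb; ++p) {
            const double x = B(p, 0), y = B(p, 1);
            Bt(p, 0) = s * (co * x - si * y) + dxs[ix];
            Bt(p, 1) = s * (si * x + co * y) + dys[iy];
          }
          double d;
          if (measure == 0) d = cpp_emd(A, Bt);
          else if (measure == 1) d = cpp_hed_equal(A, Bt);
          else {
            std::vector<char> mb((size_t)nx * ny, 0);
            fill_mask(Bt, x0, y0, cx, cy, nx, ny, mb);
            long inter = 0, sb = 0;
            for (size_t k = 0; k < mb.size(); ++k) {
              sb += mb[k];
              if (mb[k] && maskA[k]) ++inter;
            }
            d = (cntA + sb == 0) ? NA_REAL
                                 : 1.0 - 2.0 * (double)inter / (double)(cntA + sb);
          }
          if (d < best) {
            best = d; brot = rots[ir]; bdx = dxs[ix]; bdy = dys[iy]; bsc = s;
          }
        }
      }
    }
  }
  return NumericVector::create(best, brot, bdx, bdy, bsc);
}

// Distance from a point to the closed polygon boundary (all edges, including
// the baseline closure).
static double dist_to_boundary(const NumericMatrix& P, double px, double py) {
  const int n = P.nrow();
  double best = R_PosInf;
  for (int e = 0; e < n; ++e) {
    const int f = (e + 1) % n;
    const double x1 = P(e, 0), y1 = P(e, 1), x2 = P(f, 0), y2 = P(f, 1);
    const double vx = x2 - x1, vy = y2 - y1;
    const double L2 = vx * vx + vy * vy;
    double t = L2 > 0 ? ((px - x1) * vx + (py - y1) * vy) / L2 : 0.0;
    if (t < 0) t = 0; if (t > 1) t = 1;
    const double dx = px - (x1 + t * vx), dy = py - (y1 + t * vy);
    const double d2 = dx * dx + dy * dy;
    if (d2 < best) best = d2;
  }
  return std::sqrt(best);
}

static bool point_in_poly(const NumericMatrix& P, double px, double py) {
  const int n = P.nrow();
  bool in = false;
  for (int e = 0; e < n; ++e) {
    const int f = (e + 1) % n;
    const double y1 = P(e, 1), y2 = P(f, 1);
    if ((y1 <= py && y2 > py) || (y2 <= py && y1 > py)) {
      const double xint = P(e, 0) + (py - y1) / (y2 - y1) * (P(f, 0) - P(e, 0));
      if (px < xint) in = !in;
    }
  }
  return in;
}

// Radius of the largest circle inscribed in the baseline-closed polygon:
// grid search over interior points maximizing distance to the boundary,
// followed by local refinement passes.
// [[Rcpp::export]]
double cpp_inradius(const NumericMatrix& P, int grid, int refine_levels) {
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < P.nrow(); ++i) {
    xmin = std::min(xmin, P(i, 0)); xmax = std::max(xmax, P(i, 0));
    ymin = std::min(ymin, P(i, 1)); ymax = std::max(ymax, P(i, 1));
  }
  double cx0 = xmin, cy0 = ymin, w = xmax - xmin, h = ymax - ymin;
  double best = -1.0, bx = 0.5 * (xmin + xmax), by = 0.5 * (ymin + ymax);
  for (int i = 0; i < grid; ++i) {
    const double px = cx0 + (i + 0.5) / grid * w;
    for (int j = 0; j < grid; ++j) {
      const double py = cy0 + (j + 0.5) / grid * h;
      if (!point_in_poly(P, px, py)) continue;
      const double d = dist_to_boundary(P, px, py);
      if (d > best) { best = d; bx = px; by = py; }
    }
  }
  double step = std::max(w, h) / grid;
  for (int lev = 0; lev < refine_levels; ++lev) {
    step *= 0.5;
    const int m = 8;
    double nbx = bx, nby = by;
    for (int i = -m; i <= m; ++i) {
      for (int j = -m; j <= m; ++j) {
        const double px = bx + i * step / m, py = by + j * step / m;
        if (!point_in_poly(P, px, py)) continue;
        const double d = dist_to_boundary(P, px, py);
        if (d > best) { best = d; nbx = px; nby = py; }
      }
    }
    bx = nbx; by = nby;
  }
  return best;
}
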