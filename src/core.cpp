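#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Accumulate kernel-mask contributions of sparse nonzeros onto a dense grid.
// Coordinates are 0-based; the kernel is a (2R+1) x (2R+1) mask. Contributions
// falling outside the grid are dropped (zero padding). The accumulation order
// (outer loop over nonzeros in input order) is deterministic, so windowed and
// whole-grid evaluation give bitwise-identical sums for interior pixels.
// [[Rcpp::export]]
NumericMatrix kde_accumulate(const IntegerVector& row, const IntegerVector& col,
                             const NumericVector& count, int nrow, int ncol,
                             const NumericMatrix& kernel) {
  if (kernel.nrow() != kernel.ncol() || kernel.nrow() % 2 == 0)
    stop("kernel mask must be square with odd side length");
  const int R = (kernel.nrow() - 1) / 2;
  NumericMatrix out(nrow, ncol);
  const int n = row.size();
  for (int k = 0; k < n; ++k) {
    const int r0 = row[k], c0 = col[k];
    const double v = count[k];
    const int rlo = std::max(0, r0 - R), rhi = std::min(nrow - 1, r0 + R);
    const int clo = std::max(0, c0 - R), chi = std::min(ncol - 1, c0 + R);
    for (int c = clo; c <= chi; ++c) {
      const int kc = c - c0 + R;
      for (int r = rlo; r <= rhi; ++r) {
        out(r, c) += v * kernel(r - r0 + R, kc);
      }
    }
  }
  return out;
}

// For every pixel (0-based integer coordinates) return the index (1-based) of
// the nearest center by squared Euclidean distance; ties go to the lowest
// center index.
// [[Rcpp::export]]
IntegerMatrix nearest_center(int nrow, int ncol, const NumericVector& center_row,
                             const NumericVector& center_col) {
  const int m = center_row.size();
  if (m == 0) stop("at least one center required");
  IntegerMatrix out(nrow, ncol);
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      double best = R_PosInf;
      int bi = 0;
      for (int k = 0; k < m; ++k) {
        const double dr = r - center_row[k], dc = c - center_col[k];
        const double d2 = dr * dr + dc * dc;
        if (d2 < best) { best = d2; bi = k; }
      }
      out(r, c) = bi + 1;
    }
  }
  return out;
}

// Sliding Chebyshev (square window) maximum filter of radius d; values outside
// the grid are treated as -Inf.
// [[Rcpp::export]]
NumericMatrix chebyshev_max_filter(const NumericMatrix& x, int d) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = R_NegInf;
      const int rlo = std::max(0, r - d), rhi = std::min(nr - 1, r + d);
      const int clo = std::max(0, c - d), chi = std::min(nc - 1, c + d);
      for (int cc = clo; cc <= chi; ++cc)
        for (int rr = rlo; rr <= rhi; ++rr)
          if (x(rr, cc) > m) m = x(rr, cc);
      out(r, c) = m;
    }
  }
  return out;
}

// Label 8-connected components of a logical mask with integers 1..K in
// scan order (first-touched component gets the lowest label); 0 elsewhere.
// [[Rcpp::export]]
IntegerMatrix label_components8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        const int cr = q.front().first, cc = q.front().second;
        q.pop();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            const int rr = cr + dr, c2 = cc + dc;
            if (rr < 0 || rr >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(rr, c2) && lab(rr, c2) == 0) {
              lab(rr, c2) = next;
              q.push(std::make_pair(rr, c2));
            }
          }
        }
      }
    }
  }
  return lab;
}
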