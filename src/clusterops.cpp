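#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labeling of the non-zero pixels of `mask` by BFS.
// Labels are assigned in column-major scan order; 0 marks background.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> qr(H * (size_t)W), qc(H * (size_t)W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      qr[tail] = r0; qc[tail] = c0; ++tail;
      lab(r0, c0) = next;
      while (head < tail) {
        const int r = qr[head], c = qc[head]; ++head;
        for (int k = 0; k < nn; ++k) {
          const int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            qr[tail] = r2; qc[tail] = c2; ++tail;
          }
        }
      }
    }
  }
  return lab;
}

// For each point (row of `pts`, as (row, col)), the minimum Euclidean
// distance to each point set in `comps` (list of n_i x 2 matrices).
// [[Rcpp::export]]
NumericMatrix cross_min_dists_cpp(const NumericMatrix& pts, const List& comps) {
  const int n = pts.nrow(), m = comps.size();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    NumericMatrix cj = comps[j];
    const int nj = cj.nrow();
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      const double pr = pts(i, 0), pc = pts(i, 1);
      for (int k = 0; k < nj; ++k) {
        const double d1 = pr - cj(k, 0), d2 = pc - cj(k, 1);
        const double d = d1 * d1 + d2 * d2;
        if (d < best) best = d;
      }
      out(i, j) = std::sqrt(best);
    }
  }
  return out;
}

// Minimum pairwise Euclidean distance between two point sets.
// [[Rcpp::export]]
double min_set_dist_cpp(const NumericMatrix& a, const NumericMatrix& b) {
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i) {
    const double ar = a(i, 0), ac = a(i, 1);
    for (int j = 0; j < b.nrow(); ++j) {
      const double d1 = ar - b(j, 0), d2 = ac - b(j, 1);
      const double d = d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
  }
  return std::sqrt(best);
}
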