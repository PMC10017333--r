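#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Variable-window local-maxima scan over a canopy height model.
// A cell is an apex candidate iff its height >= min_height and it is the
// strict maximum within a circular window whose radius (metres) is
// clamp(a + b * height, r_min, r_max); ties go to the first cell in
// row-major order. Returns a 3-column matrix (row, col, height), 1-based.
// [[Rcpp::export]]
NumericMatrix detect_maxima_cpp(NumericMatrix chm, double res,
                                double min_height, double a, double b,
                                double r_min, double r_max) {
  const int nr = chm.nrow(), nc = chm.ncol();
  std::vector<double> out_r, out_c, out_h;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const double h = chm(r, c);
      if (!(h >= min_height)) continue;
      double rad = a + b * h;
      if (rad < r_min) rad = r_min;
      if (rad > r_max) rad = r_max;
      const double rpx = rad / res;
      const int w = (int)std::floor(rpx);
      bool is_max = true;
      for (int dr = -w; dr <= w && is_max; ++dr) {
        const int rr = r + dr;
        if (rr < 0 || rr >= nr) continue;
        for (int dc = -w; dc <= w; ++dc) {
          if (dr == 0 && dc == 0) continue;
          const int cc = c + dc;
          if (cc < 0 || cc >= nc) continue;
          if ((double)dr * dr + (double)dc * dc > rpx * rpx) continue;
          const double hn = chm(rr, cc);
          if (hn > h || (hn == h && (rr < r || (rr == r && cc < c)))) {
            is_max = false;
            break;
          }
        }
      }
      if (is_max) {
        out_r.push_back(r + 1);
        out_c.push_back(c + 1);
        out_h.push_back(h);
      }
    }
  }
  NumericMatrix out(out_r.size(), 3);
  for (size_t i = 0; i < out_r.size(); ++i) {
    out(i, 0) = out_r[i];
    out(i, 1) = out_c[i];
    out(i, 2) = out_h[i];
  }
  return out;
}

// Region-growing crown segmentation in the style of the classic
// CHM-based individual-tree delineation: crowns grow from apexes processed
// tallest-first (caller sorts), admitting 4-connected neighbours whose CHM
// exceeds both seed_frac * apex height and crown_frac * the current crown
// mean height, never farther than max_radius (m) from the apex and never
// into an already-claimed cell (first claim wins). Returns an integer claim
// matrix: 0 = unclaimed, k = crown of the k-th supplied apex.
// [[Rcpp::export]]
IntegerMatrix grow_crowns_cpp(NumericMatrix chm, IntegerVector apex_row,
                              IntegerVector apex_col, double res,
                              double seed_frac, double crown_frac,
                              double max_radius) {
  const int nr = chm.nrow(), nc = chm.ncol();
  const int n = apex_row.size();
  IntegerMatrix claim(nr, nc);
  const double rpx2 = (max_radius / res) * (max_radius / res);
  const int drs[4] = {-1, 1, 0, 0};
  const int dcs[4] = {0, 0, -1, 1};
  for (int k = 0; k < n; ++k) {
    const int ar = apex_row[k] - 1, ac = apex_col[k] - 1;
    if (claim(ar, ac) != 0) continue; // apex swallowed by an earlier crown
    const double ah = chm(ar, ac);
    double sum = ah;
    int cnt = 1;
    claim(ar, ac) = k + 1;
    std::queue<std::pair<int, int> > q;
    q.push(std::make_pair(ar, ac));
    while (!q.empty()) {
      const int r = q.front().first, c = q.front().second;
      q.pop();
      for (int d = 0; d < 4; ++d) {
        const int rr = r + drs[d], cc = c + dcs[d];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (claim(rr, cc) != 0) continue;
        const double dr = rr - ar, dc = cc - ac;
        if (dr * dr + dc * dc > rpx2) continue;
        const double h = chm(rr, cc);
        if (h <= seed_frac * ah) continue;
        if (h <= crown_frac * (sum / cnt)) continue;
        claim(rr, cc) = k + 1;
        sum += h;
        ++cnt;
        q.push(std::make_pair(rr, cc));
      }
    }
  }
  return claim;
}
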