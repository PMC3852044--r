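#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap Smith-Waterman with full traceback.
// a, b: 0-based codes into `mat` rows/cols. A gap of length L costs
// gap_open + L * gap_extend (the first gap column pays gap_open +
// gap_extend, matching the BLAST "existence 11 / extension 1" convention).
// Returns the optimal local alignment score, 1-based coordinates of the
// aligned region, and per-column paths (index into sequence, 0 = gap).

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix mat,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double open_cost = gap_open + gap_extend;
  // states: M = residue vs residue, X = gap in subject (consumes a),
  //         Y = gap in query (consumes b)
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  // traceback codes: for M 0=fresh start, 1=from M, 2=from X, 3=from Y
  // (predecessor at i-1,j-1); for X/Y 1=opened from M, 2=extended
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbY((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  char bstate = 'M';

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = at(i, j);
      { // X: gap run in subject, consuming a[i-1]; may follow a Y run
        double from_m = M[at(i - 1, j)] - open_cost;
        double from_x = X[at(i - 1, j)] - gap_extend;
        double from_y = Y[at(i - 1, j)] - open_cost;
        X[ij] = from_m; tbX[ij] = 1;
        if (from_x > X[ij]) { X[ij] = from_x; tbX[ij] = 2; }
        if (from_y > X[ij]) { X[ij] = from_y; tbX[ij] = 3; }
      }
      { // Y: gap run in query, consuming b[j-1]; may follow an X run
        double from_m = M[at(i, j - 1)] - open_cost;
        double from_y = Y[at(i, j - 1)] - gap_extend;
        double from_x = X[at(i, j - 1)] - open_cost;
        Y[ij] = from_m; tbY[ij] = 1;
        if (from_y > Y[ij]) { Y[ij] = from_y; tbY[ij] = 2; }
        if (from_x > Y[ij]) { Y[ij] = from_x; tbY[ij] = 3; }
      }
      { // M: consume both; a fresh local start competes with continuation
        const double s = mat(a[i - 1], b[j - 1]);
        const int d = at(i - 1, j - 1);
        double val = (s > 0.0) ? s : 0.0; // fresh start (or dead cell)
        unsigned char tb = 0;
        if (M[d] > 0.0 && M[d] + s > val) { val = M[d] + s; tb = 1; }
        if (X[d] + s > val) { val = X[d] + s; tb = 2; }
        if (Y[d] + s > val) { val = Y[d] + s; tb = 3; }
        M[ij] = val; tbM[ij] = tb;
      }
      if (M[ij] > best) { best = M[ij]; bi = i; bj = j; bstate = 'M'; }
      if (X[ij] > best) { best = X[ij]; bi = i; bj = j; bstate = 'X'; }
      if (Y[ij] > best) { best = Y[ij]; bi = i; bj = j; bstate = 'Y'; }
    }
  }

  std::vector<int> qpath, spath; // filled backwards
  if (best > 0.0) {
    int i = bi, j = bj;
    char st = bstate;
    bool done = false;
    while (!done) {
      const int ij = at(i, j);
      if (st == 'M') {
        qpath.push_back(i); spath.push_back(j);
        const unsigned char tb = tbM[ij];
        --i; --j;
        if (tb == 0) done = true;          // fresh local start: stop here
        else st = (tb == 1) ? 'M' : (tb == 2 ? 'X' : 'Y');
      } else if (st == 'X') {
        qpath.push_back(i); spath.push_back(0);
        const unsigned char tb = tbX[ij];
        --i;
        st = (tb == 1) ? 'M' : (tb == 2 ? 'X' : 'Y');
      } else {
        qpath.push_back(0); spath.push_back(j);
        const unsigned char tb = tbY[ij];
        --j;
        st = (tb == 1) ? 'M' : (tb == 2 ? 'Y' : 'X');
      }
    }
    std::reverse(qpath.begin(), qpath.end());
    std::reverse(spath.begin(), spath.end());
  }

  int q_start = 0, q_end = 0, s_start = 0, s_end = 0;
  for (size_t k = 0; k < qpath.size(); ++k) {
    if (qpath[k] > 0) { if (q_start == 0) q_start = qpath[k]; q_end = qpath[k]; }
    if (spath[k] > 0) { if (s_start == 0) s_start = spath[k]; s_end = spath[k]; }
  }

  return List::create(_["score"] = best,
                      _["q_start"] = q_start, _["q_end"] = q_end,
                      _["s_start"] = s_start, _["s_end"] = s_end,
                      _["query_path"] = wrap(qpath),
                      _["subject_path"] = wrap(spath));
}
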