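#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh), on integer-encoded
// peptides (0-based indices into the substitution matrix).  Gap of length k
// costs open + k * extend (NCBI convention).  Tie-break on equal score:
// smallest query end, then smallest target end.
//
// Returns: score, q_start, q_end, t_start, t_end (0-based half-open),
// n_match, n_cols (aligned columns incl. gaps).
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector t, IntegerMatrix sub,
                  double gap_open, double gap_extend) {
  const int m = q.size(), n = t.size();
  if (m == 0 || n == 0) stop("empty sequence in local alignment");
  const double NEG = -1e30;
  const double gfirst = gap_open + gap_extend;

  // DP row-wise over query; full matrices kept for traceback.
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), NEG);  // gap in query (consumes t)
  std::vector<double> F((m + 1) * (n + 1), NEG);  // gap in target (consumes q)
  // traceback code for H: 0 stop, 1 diag, 2 from E, 3 from F
  std::vector<unsigned char> TB((m + 1) * (n + 1), 0);
  std::vector<unsigned char> TE((m + 1) * (n + 1), 0); // 1: E extends E
  std::vector<unsigned char> TF((m + 1) * (n + 1), 0); // 1: F extends F

  double best = 0.0;
  int bi = 0, bj = 0;
  const int ncol = n + 1;

  for (int i = 1; i <= m; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int idx = i * ncol + j;
      double eo = H[idx - 1] - gfirst;
      double ee = E[idx - 1] - gap_extend;
      if (ee > eo) { E[idx] = ee; TE[idx] = 1; } else { E[idx] = eo; TE[idx] = 0; }
      double fo = H[idx - ncol] - gfirst;
      double fe = F[idx - ncol] - gap_extend;
      if (fe > fo) { F[idx] = fe; TF[idx] = 1; } else { F[idx] = fo; TF[idx] = 0; }
      double diag = H[idx - ncol - 1] + sub(qi, t[j - 1]);
      double h = 0.0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[idx] > h) { h = E[idx]; tb = 2; }
      if (F[idx] > h) { h = F[idx]; tb = 3; }
      H[idx] = h; TB[idx] = tb;
      // strictly greater: keeps the smallest (q_end, t_end) on ties because
      // we scan i (query) outermost and j (target) innermost in increasing
      // order -- the first cell reaching `best` wins.
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj)
  int i = bi, j = bj;
  int nmatch = 0, ncols = 0;
  int state = 0; // 0 in H, 1 in E, 2 in F
  while (i > 0 && j > 0) {
    const int idx = i * ncol + j;
    if (state == 0) {
      unsigned char tb = TB[idx];
      if (tb == 0) break;
      if (tb == 1) {
        if (q[i - 1] == t[j - 1]) ++nmatch;
        ++ncols; --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++ncols;
      if (TE[idx] == 0) state = 0;
      --j;
    } else {
      ++ncols;
      if (TF[idx] == 0) state = 0;
      --i;
    }
  }

  return List::create(
    _["score"] = best,
    _["q_start"] = i, _["q_end"] = bi,
    _["t_start"] = j, _["t_end"] = bj,
    _["n_match"] = nmatch, _["n_cols"] = ncols);
}
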