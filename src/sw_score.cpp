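#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment scores (affine gaps: a gap of length g
// costs gap_open + g * gap_ext, matching Biostrings::pairwiseAlignment).
// Sequences are pre-encoded as 0-based indices into the substitution
// matrix.  Score-only: used for the mass screening step of the translated
// search; full alignments of passing pairs are recomputed in R.
// [[Rcpp::export]]
NumericVector sw_scores_cpp(List queries, IntegerVector subject,
                            NumericMatrix submat, double gap_open,
                            double gap_ext) {
  const int n = queries.size();
  const int m = subject.size();
  NumericVector out(n);
  const double og = gap_open + gap_ext;
  const double neg = -1e30;
  const int nrow = submat.nrow();
  const double* sub = REAL(submat);
  const int* sj = INTEGER(subject);
  std::vector<double> H(m + 1), E(m + 1);
  for (int q = 0; q < n; ++q) {
    IntegerVector qsv = queries[q];
    const int L = qsv.size();
    const int* qs = INTEGER(qsv);
    std::fill(H.begin(), H.end(), 0.0);
    std::fill(E.begin(), E.end(), neg);
    double* h_ = H.data();
    double* e_ = E.data();
    double best = 0.0;
    for (int i = 1; i <= L; ++i) {
      double diag = 0.0;
      double F = neg;
      const double* srow = sub + qs[i - 1];
      for (int j = 1; j <= m; ++j) {
        const double up = h_[j];
        double e = h_[j] - og;
        const double e2 = e_[j] - gap_ext;
        if (e2 > e) e = e2;
        e_[j] = e;
        double f = h_[j - 1] - og;
        const double f2 = F - gap_ext;
        if (f2 > f) f = f2;
        F = f;
        double h = diag + srow[(size_t)nrow * sj[j - 1]];
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0.0) h = 0.0;
        diag = up;
        h_[j] = h;
        if (h > best) best = h;
      }
    }
    out[q] = best;
  }
  return out;
}

// Full Smith-Waterman local alignment with affine-gap traceback.
// Returns the best score, 1-based spans, and the move sequence
// (1 = substitution column, 2 = query residue vs gap, 3 = gap vs subject
// residue).  Ties prefer substitution, then the query-gap state, giving a
// deterministic path.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector query, IntegerVector subject,
                  NumericMatrix submat, double gap_open, double gap_ext) {
  const int L = query.size(), m = subject.size();
  const double og = gap_open + gap_ext;
  const double neg = -1e30;
  const int nrow = submat.nrow();
  const double* sub = REAL(submat);
  const int* qs = INTEGER(query);
  const int* sj = INTEGER(subject);
  std::vector<double> Hp(m + 1, 0.0), Hc(m + 1, 0.0), E(m + 1, neg);
  // per-cell packed directions: bits 0-1 H source (0 stop, 1 diag, 2 E,
  // 3 F), bit 2 E extends, bit 3 F extends
  std::vector<unsigned char> dir((size_t)(L + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= L; ++i) {
    const double* srow = sub + qs[i - 1];
    double F = neg;
    Hc[0] = 0.0;
    unsigned char* drow = dir.data() + (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      unsigned char d = 0;
      double e_open = Hp[j] - og, e_ext = E[j] - gap_ext;
      double e = e_open;
      if (e_ext > e_open) { e = e_ext; d |= 4; }
      E[j] = e;
      double f_open = Hc[j - 1] - og, f_ext = F - gap_ext;
      double f = f_open;
      if (f_ext > f_open) { f = f_ext; d |= 8; }
      F = f;
      double hdiag = Hp[j - 1] + srow[(size_t)nrow * sj[j - 1]];
      double h = 0.0; int src = 0;
      if (hdiag > h) { h = hdiag; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      d |= (unsigned char)src;
      drow[j] = d;
      Hc[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hp, Hc);
    std::fill(Hc.begin(), Hc.end(), 0.0);
  }
  std::vector<int> ops;
  int i = bi, j = bj, state = 0;  // 0 = H, 2 = E, 3 = F
  if (best > 0.0) {
    while (i > 0 && j > 0) {
      unsigned char d = dir[(size_t)i * (m + 1) + j];
      if (state == 0) {
        int src = d & 3;
        if (src == 0) break;
        if (src == 1) { ops.push_back(1); --i; --j; }
        else state = src;
      } else if (state == 2) {
        ops.push_back(2);
        state = (d & 4) ? 2 : 0;
        --i;
      } else {
        ops.push_back(3);
        state = (d & 8) ? 3 : 0;
        --j;
      }
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best,
                      _["q_span"] = IntegerVector::create(i + 1, bi),
                      _["s_span"] = IntegerVector::create(j + 1, bj),
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
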