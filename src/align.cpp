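#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap Smith-Waterman. Gap of length L costs open + ext * L
// (BLAST convention). Sequences arrive as 0-based integer codes into
// the substitution matrix. Scores are integer-valued throughout.

// [[Rcpp::export(name = ".sw_score")]]
int sw_score(const IntegerVector& a, const IntegerVector& b,
             const IntegerMatrix& S, int gap_open, int gap_ext) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const int open_cost = gap_open + gap_ext;
  std::vector<int> H(n + 1, 0), E(n + 1, INT_MIN / 4);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int diag = 0;      // H[i-1][j-1]
    int F = INT_MIN / 4;
    int Hij_left = 0;  // H[i][j-1]
    const int ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      E[j] = std::max(Hij_left - open_cost, E[j] - gap_ext);
      F = std::max(H[j] - open_cost, F - gap_ext);
      int h = diag + S(ai, b[j - 1]);
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      Hij_left = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full alignment with traceback. Best cell = maximum score; ties broken
// by the smallest query end, then smallest target end (first strictly
// greater update in row-major scan). Traceback prefers diagonal, then
// gap-in-target (up), then gap-in-query (left).
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(const IntegerVector& a, const IntegerVector& b,
              const IntegerMatrix& S, int gap_open, int gap_ext) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const int open_cost = gap_open + gap_ext;
  const int NEG = INT_MIN / 4;
  const size_t W = n + 1;
  std::vector<int> H((m + 1) * W, 0), E((m + 1) * W, NEG), F((m + 1) * W, NEG);
  // ptrH: 0 = stop, 1 = diag, 2 = from E (left), 3 = from F (up)
  std::vector<unsigned char> ptrH((m + 1) * W, 0), extE((m + 1) * W, 0),
      extF((m + 1) * W, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int ai = a[i - 1];
    const size_t row = i * W, prev = (i - 1) * W;
    for (int j = 1; j <= n; ++j) {
      int e_open = H[row + j - 1] - open_cost;
      int e_ext = E[row + j - 1] - gap_ext;
      if (e_ext > e_open) { E[row + j] = e_ext; extE[row + j] = 1; }
      else E[row + j] = e_open;
      int f_open = H[prev + j] - open_cost;
      int f_ext = F[prev + j] - gap_ext;
      if (f_ext > f_open) { F[row + j] = f_ext; extF[row + j] = 1; }
      else F[row + j] = f_open;
      int h = H[prev + j - 1] + S(ai, b[j - 1]);
      unsigned char p = 1;
      if (F[row + j] > h) { h = F[row + j]; p = 3; }
      if (E[row + j] > h) { h = E[row + j]; p = 2; }
      if (h <= 0) { h = 0; p = 0; }
      H[row + j] = h;
      ptrH[row + j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best == 0)
    return List::create(_["score"] = 0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER, _["sstart"] = NA_INTEGER,
                        _["send"] = NA_INTEGER, _["length"] = 0,
                        _["n_ident"] = 0, _["gaps"] = 0, _["gapopen"] = 0);
  int i = bi, j = bj, n_ident = 0, alen = 0, gaps = 0, gapopen = 0;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (true) {
    const size_t row = (size_t)i * W;
    if (state == 0) {
      unsigned char p = ptrH[row + j];
      if (p == 0) break;
      if (p == 1) {
        ++alen;
        if (a[i - 1] == b[j - 1]) ++n_ident;
        --i; --j;
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // gap in query, consumes target
      ++alen; ++gaps;
      if (!extE[row + j]) { state = 0; ++gapopen; }
      --j;
    } else {  // gap in target, consumes query
      ++alen; ++gaps;
      if (!extF[row + j]) { state = 0; ++gapopen; }
      --i;
    }
  }
  return List::create(_["score"] = best, _["qstart"] = i + 1,
                      _["qend"] = bi, _["sstart"] = j + 1, _["send"] = bj,
                      _["length"] = alen, _["n_ident"] = n_ident,
                      _["gaps"] = gaps, _["gapopen"] = gapopen);
}

// Score-only all-vs-all: rows = queries, cols = targets.
// [[Rcpp::export(name = ".sw_score_matrix")]]
IntegerMatrix sw_score_matrix(const List& qs, const List& ts,
                              const IntegerMatrix& S, int gap_open,
                              int gap_ext) {
  const int nq = qs.size(), nt = ts.size();
  IntegerMatrix out(nq, nt);
  std::vector<IntegerVector> tv(nt);
  for (int j = 0; j < nt; ++j) tv[j] = ts[j];
  for (int i = 0; i < nq; ++i) {
    IntegerVector q = qs[i];
    for (int j = 0; j < nt; ++j) {
      out(i, j) = sw_score(q, tv[j], S, gap_open, gap_ext);
      Rcpp::checkUserInterrupt();
    }
  }
  return out;
}
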