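// Recombination summary statistics over nucleotide alignments.
//
// Site-pair incompatibility is measured as the cycle rank (e - v + c) of
// the partition intersection graph over observed joint states: 0 for a
// compatible pair, >0 when extra homoplastic changes are required to fit
// both sites on one tree.  PHI averages this score over informative-site
// pairs within a nucleotide window; NSS is the fraction of adjacent
// informative-site pairs that are compatible; MaxChi scans, for every
// sequence pair, breakpoints between consecutive pairwise differences and
// contrasts difference density left vs right with a 2x2 chi-squared.
#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

// x, y: state columns coded 0..3, negative = missing; returns e - v + c
int cycle_rank(const int* x, const int* y, int nseq) {
  bool edge[4][4] = {{false}};
  int e = 0;
  for (int i = 0; i < nseq; ++i) {
    const int a = x[i], b = y[i];
    if (a < 0 || b < 0) continue;
    if (!edge[a][b]) { edge[a][b] = true; ++e; }
  }
  // union-find over 8 vertices: states of x (0..3), states of y (4..7)
  int parent[8];
  bool used[8] = {false};
  for (int i = 0; i < 8; ++i) parent[i] = i;
  struct UF {
    int* p;
    int find(int i) { while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; } return i; }
  } uf = {parent};
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      if (edge[a][b]) {
        used[a] = used[4 + b] = true;
        const int ra = uf.find(a), rb = uf.find(4 + b);
        if (ra != rb) parent[ra] = rb;
      }
  int v = 0, c = 0;
  for (int i = 0; i < 8; ++i)
    if (used[i]) {
      ++v;
      if (uf.find(i) == i) ++c;
    }
  return e - v + c;
}

}  // namespace

// snp: nseq x nsites informative-site matrix (0..3, negative missing);
// pos: nucleotide position of each column; window: max position distance
// [[Rcpp::export]]
double cpp_phi(IntegerMatrix snp, IntegerVector pos, int window) {
  const int m = snp.ncol(), nseq = snp.nrow();
  if (m < 2) return 0.0;
  std::vector<std::vector<int>> col(m, std::vector<int>(nseq));
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < nseq; ++i) col[j][i] = snp(i, j);
  double sum = 0.0;
  long count = 0;
  for (int j = 0; j < m; ++j)
    for (int k = j + 1; k < m; ++k) {
      if (pos[k] - pos[j] > window) break;
      sum += cycle_rank(col[j].data(), col[k].data(), nseq);
      ++count;
    }
  return count > 0 ? sum / count : 0.0;
}

// [[Rcpp::export]]
double cpp_nss(IntegerMatrix snp) {
  const int m = snp.ncol(), nseq = snp.nrow();
  if (m < 2) return 0.0;
  std::vector<int> a(nseq), b(nseq);
  int compat = 0;
  for (int j = 0; j + 1 < m; ++j) {
    for (int i = 0; i < nseq; ++i) { a[i] = snp(i, j); b[i] = snp(i, j + 1); }
    if (cycle_rank(a.data(), b.data(), nseq) == 0) ++compat;
  }
  return static_cast<double>(compat) / (m - 1);
}

// nt: nseq x l nucleotide matrix (0..3, negative missing); k: window in
// polymorphic sites per side.  Candidate breakpoints lie between
// consecutive polymorphic columns of the alignment; for each sequence
// pair the 2x2 chi-squared contrasts the pair's differences vs
// identities at the k polymorphic sites on each side (truncated at the
// ends).
// [[Rcpp::export]]
double cpp_maxchi(IntegerMatrix nt, int k) {
  const int nseq = nt.nrow(), l = nt.ncol();

  // polymorphic columns of the whole alignment
  std::vector<int> poly;
  for (int p = 0; p < l; ++p) {
    int first = -1;
    bool seg = false;
    for (int i = 0; i < nseq; ++i) {
      const int a = nt(i, p);
      if (a < 0) continue;
      if (first < 0) first = a;
      else if (a != first) { seg = true; break; }
    }
    if (seg) poly.push_back(p);
  }
  const int np = static_cast<int>(poly.size());
  if (np < 2) return 0.0;

  double best = 0.0;
  std::vector<int> cum(np + 1), cmp(np + 1);  // prefix sums: diffs, valid
  for (int i = 0; i < nseq; ++i)
    for (int j = i + 1; j < nseq; ++j) {
      cum[0] = cmp[0] = 0;
      for (int m = 0; m < np; ++m) {
        const int a = nt(i, poly[m]), b = nt(j, poly[m]);
        const bool ok = a >= 0 && b >= 0;
        cum[m + 1] = cum[m] + (ok && a != b ? 1 : 0);
        cmp[m + 1] = cmp[m] + (ok ? 1 : 0);
      }
      for (int m = 1; m < np; ++m) {  // breakpoint before poly site m
        const int lo = std::max(0, m - k);
        const int hi = std::min(np, m + k);
        const double dl = cum[m] - cum[lo];
        const double nl = cmp[m] - cmp[lo];
        const double dr = cum[hi] - cum[m];
        const double nr = cmp[hi] - cmp[m];
        const double a2 = nl - dl, b2 = nr - dr;
        const double colsame = a2 + b2, coldiff = dl + dr;
        if (nl <= 0.0 || nr <= 0.0 || colsame <= 0.0 || coldiff <= 0.0)
          continue;
        const double tot = nl + nr;
        const double det = dl * b2 - dr * a2;
        const double chi2 = tot * det * det / (nl * nr * colsame * coldiff);
        if (chi2 > best) best = chi2;
      }
    }
  return best;
}
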