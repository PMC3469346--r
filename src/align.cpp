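#include <Rcpp.h>
using namespace Rcpp;

// Fitting (glocal) alignment of b inside a with linear gap costs: all of b
// is consumed; the unaligned prefix/suffix of a are free terminal gaps.
// Returns score and traceback endpoints.
struct Fit {
  double score;
  std::string aa, bb;
  int a_start, a_end;
};

static Fit fit_b_in_a(const std::string& a, const std::string& b,
                      double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 0 diag, 1 up (gap in b), 2 left (gap in a)
  for (int i = 1; i <= n; ++i) { S(i, 0) = 0.0; P(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; P(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = S(i - 1, j) + gap;
      double l = S(i, j - 1) + gap;
      if (d >= u && d >= l)      { S(i, j) = d; P(i, j) = 0; }
      else if (u >= l)           { S(i, j) = u; P(i, j) = 1; }
      else                       { S(i, j) = l; P(i, j) = 2; }
    }
  }
  int bi = n;
  double best = S(n, m);
  for (int i = 0; i <= n; ++i)
    if (S(i, m) > best) { best = S(i, m); bi = i; }
  std::string aa, bb;
  int i = bi, j = m;
  while (j > 0) {
    int p = P(i, j);
    if (i == 0) p = 2;
    if (p == 0)      { aa += a[i - 1]; bb += b[j - 1]; --i; --j; }
    else if (p == 1) { aa += a[i - 1]; bb += '-';      --i; }
    else             { aa += '-';      bb += b[j - 1]; --j; }
  }
  // stop once all of b is consumed: remaining prefix of a is a free end gap
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  Fit f;
  f.score = best; f.aa = aa; f.bb = bb; f.a_start = i; f.a_end = bi;
  return f;
}

// Pairwise alignment where the end gaps are free in one sequence only (the
// shorter sequence "fits" inside the longer; both orientations are tried and
// the better-scoring one returned). Identity is matches over aligned columns,
// free terminal gaps excluded.
//
// [[Rcpp::export(name = ".nw_overlap")]]
List nw_overlap(std::string a, std::string b,
                double match = 1.0, double mismatch = -1.0, double gap = -2.0) {
  Fit f1 = fit_b_in_a(a, b, match, mismatch, gap);  // b inside a
  Fit f2 = fit_b_in_a(b, a, match, mismatch, gap);  // a inside b
  bool use1 = f1.score > f2.score;
  if (f1.score == f2.score) {
    int m1 = 0, m2 = 0;
    for (size_t k = 0; k < f1.aa.size(); ++k) if (f1.aa[k] == f1.bb[k]) ++m1;
    for (size_t k = 0; k < f2.aa.size(); ++k) if (f2.aa[k] == f2.bb[k]) ++m2;
    use1 = m1 >= m2;
  }
  std::string aa = use1 ? f1.aa : f2.bb;
  std::string bb = use1 ? f1.bb : f2.aa;
  double score = use1 ? f1.score : f2.score;
  int a_start = use1 ? f1.a_start : 0;
  int a_end   = use1 ? f1.a_end : (int)a.size();
  int b_start = use1 ? 0 : f2.a_start;
  int b_end   = use1 ? (int)b.size() : f2.a_end;

  int matches = 0, cols = aa.size();
  for (int k = 0; k < cols; ++k) if (aa[k] == bb[k]) ++matches;
  double identity = cols > 0 ? (double)matches / cols : NA_REAL;

  return List::create(
    _["score"] = score,
    _["identity"] = identity,
    _["matches"] = matches,
    _["columns"] = cols,
    _["aligned_a"] = aa,
    _["aligned_b"] = bb,
    _["a_start"] = a_start,   // 0-based half-open aligned range in a
    _["a_end"] = a_end,
    _["b_start"] = b_start,
    _["b_end"] = b_end);
}

// All-vs-one alignments, used for star alignment and clustering.
// [[Rcpp::export(name = ".nw_overlap_many")]]
List nw_overlap_many(CharacterVector seqs, std::string ref,
                     double match = 1.0, double mismatch = -1.0,
                     double gap = -2.0) {
  int n = seqs.size();
  List out(n);
  for (int k = 0; k < n; ++k)
    out[k] = nw_overlap(as<std::string>(seqs[k]), ref, match, mismatch, gap);
  return out;
}
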