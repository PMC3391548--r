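#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap cost, followed by
// distance extraction: terminal gap columns are excluded, and the distance
// is (mismatches + internal gap columns) / core columns. Scores: match +2,
// mismatch -4, gap -5 per base, so a single internal indel is preferred
// over a frame-shifted run of mismatches but not over a lone mismatch.
// Tie preference diagonal > up > left keeps the traceback deterministic.

static const int MATCH = 2, MISM = -4, GAP = -5;

static double pair_dist_ordered(const std::string &x, const std::string &y);

// canonical argument order makes the deterministic traceback, and hence the
// distance, symmetric even when co-optimal alignments exist
static double pair_dist(const std::string &a, const std::string &b) {
  if (a.size() < b.size() || (a.size() == b.size() && a <= b))
    return pair_dist_ordered(a, b);
  return pair_dist_ordered(b, a);
}

static double pair_dist_ordered(const std::string &x, const std::string &y) {
  const int n = (int)x.size(), m = (int)y.size();
  if (n == 0 || m == 0) return 1.0;
  std::vector<int> prev(m + 1), cur(m + 1);
  // traceback: 0 diag, 1 up (gap in y), 2 left (gap in x)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = GAP * j; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = GAP * i;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sd = prev[j - 1] + (x[i - 1] == y[j - 1] ? MATCH : MISM);
      int su = prev[j] + GAP;
      int sl = cur[j - 1] + GAP;
      int best = sd; unsigned char t = 0;
      if (su > best) { best = su; t = 1; }
      if (sl > best) { best = sl; t = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  // traceback -> op sequence (reversed)
  std::vector<unsigned char> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && t == 0) { ops.push_back(0); --i; --j; }
    else if (i > 0 && (t == 1 || j == 0)) { ops.push_back(1); --i; }
    else { ops.push_back(2); --j; }
  }
  // ops reversed vs alignment order, but terminal trimming is symmetric
  int first = -1, last = -1;
  for (int k = 0; k < (int)ops.size(); ++k)
    if (ops[k] == 0) { if (first < 0) first = k; last = k; }
  if (first < 0) return 1.0;
  int cols = last - first + 1, mism = 0, gaps = 0;
  // recover residue indices across the core; ops are stored 3'->5'
  int xi = 0, yj = 0; // consumed counts walking from the 3' end
  for (int k = 0; k < (int)ops.size(); ++k) {
    bool core = (k >= first && k <= last);
    if (ops[k] == 0) {
      ++xi; ++yj;
      if (core && x[n - xi] != y[m - yj]) ++mism;
    } else if (ops[k] == 1) {
      ++xi; if (core) ++gaps;
    } else {
      ++yj; if (core) ++gaps;
    }
  }
  return (double)(mism + gaps) / (double)cols;
}

// [[Rcpp::export]]
double align_dist_cpp(std::string a, std::string b) {
  return pair_dist(a, b);
}

// [[Rcpp::export]]
NumericMatrix dist_matrix_cpp(std::vector<std::string> seqs) {
  const int n = (int)seqs.size();
  NumericMatrix d(n, n);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double v = pair_dist(seqs[i], seqs[j]);
      d(i, j) = v;
      d(j, i) = v;
    }
    Rcpp::checkUserInterrupt();
  }
  return d;
}
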