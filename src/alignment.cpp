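#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Global alignment of two integer-coded EC sequences minimising total column
// cost with a linear gap penalty. Secondary objective: among minimum-cost
// alignments, maximise the number of substitution (diagonal) columns, so the
// alignment length (and hence the normalized score) is a symmetric function
// of the pair. Traceback tie-break order among optimal moves: substitution,
// then gap-in-b (consume a), then gap-in-a (consume b).

static const double EPS = 1e-12;

// fills M (min cost) and K (max diagonals among min-cost paths)
static void dp_fill(const std::vector<int>& a, const std::vector<int>& b,
                    const NumericMatrix& D, double gap,
                    std::vector<double>& M, std::vector<int>& K) {
  size_t n = a.size(), m = b.size();
  size_t W = m + 1;
  M.assign((n + 1) * W, 0.0);
  K.assign((n + 1) * W, 0);
  for (size_t i = 1; i <= n; ++i) M[i * W] = i * gap;
  for (size_t j = 1; j <= m; ++j) M[j] = j * gap;
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      double diag = M[(i - 1) * W + (j - 1)] + D(a[i - 1] - 1, b[j - 1] - 1);
      double up   = M[(i - 1) * W + j] + gap;
      double left = M[i * W + (j - 1)] + gap;
      double best = diag;
      if (up < best) best = up;
      if (left < best) best = left;
      int k = -1;
      if (diag < best + EPS) k = K[(i - 1) * W + (j - 1)] + 1;
      if (up < best + EPS) k = std::max(k, K[(i - 1) * W + j]);
      if (left < best + EPS) k = std::max(k, K[i * W + (j - 1)]);
      M[i * W + j] = best;
      K[i * W + j] = k;
    }
  }
}

static std::vector<int> as_vec(SEXP s) {
  IntegerVector v(s);
  return std::vector<int>(v.begin(), v.end());
}

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector ai, IntegerVector bi, NumericMatrix D,
                  double gap) {
  std::vector<int> a(ai.begin(), ai.end()), b(bi.begin(), bi.end());
  std::vector<double> M;
  std::vector<int> K;
  dp_fill(a, b, D, gap, M, K);
  size_t n = a.size(), m = b.size(), W = m + 1;
  std::vector<int> ca, cb;
  size_t i = n, j = m;
  while (i > 0 || j > 0) {
    bool moved = false;
    if (i > 0 && j > 0) {
      double diag = M[(i - 1) * W + (j - 1)] + D(a[i - 1] - 1, b[j - 1] - 1);
      if (std::abs(M[i * W + j] - diag) < EPS &&
          K[i * W + j] == K[(i - 1) * W + (j - 1)] + 1) {
        ca.push_back(a[i - 1]); cb.push_back(b[j - 1]); --i; --j;
        moved = true;
      }
    }
    if (!moved && i > 0 &&
        std::abs(M[i * W + j] - (M[(i - 1) * W + j] + gap)) < EPS &&
        K[i * W + j] == K[(i - 1) * W + j]) {
      ca.push_back(a[i - 1]); cb.push_back(0); --i;
      moved = true;
    }
    if (!moved) {
      ca.push_back(0); cb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ca.begin(), ca.end());
  std::reverse(cb.begin(), cb.end());
  double cost = M[n * W + m];
  int len = (int) (n + m) - K[n * W + m];
  return List::create(_["cost"] = cost, _["length"] = len,
                      _["score"] = len > 0 ? cost / len : 0.0,
                      _["a_cols"] = IntegerVector(ca.begin(), ca.end()),
                      _["b_cols"] = IntegerVector(cb.begin(), cb.end()));
}

static inline double pair_score(const std::vector<int>& a,
                                const std::vector<int>& b,
                                const NumericMatrix& D, double gap,
                                std::vector<double>& M, std::vector<int>& K) {
  dp_fill(a, b, D, gap, M, K);
  size_t n = a.size(), m = b.size(), W = m + 1;
  double cost = M[n * W + m];
  int len = (int) (n + m) - K[n * W + m];
  return len > 0 ? cost / len : 0.0;
}

// scores for an explicit list of (ii, jj) pairs into seqs (1-based indices)
// [[Rcpp::export]]
NumericVector nw_score_pairs_cpp(List seqs, IntegerVector ii, IntegerVector jj,
                                 NumericMatrix D, double gap) {
  size_t N = seqs.size();
  std::vector<std::vector<int> > S(N);
  for (size_t k = 0; k < N; ++k) S[k] = as_vec(seqs[k]);
  size_t P = ii.size();
  NumericVector out(P);
  std::vector<double> M;
  std::vector<int> K;
  for (size_t p = 0; p < P; ++p)
    out[p] = pair_score(S[ii[p] - 1], S[jj[p] - 1], D, gap, M, K);
  return out;
}

// all-vs-all upper-triangle scores, row-major order (1,2),(1,3),...,(n-1,n)
// [[Rcpp::export]]
NumericVector nw_score_all_cpp(List seqs, NumericMatrix D, double gap) {
  size_t N = seqs.size();
  std::vector<std::vector<int> > S(N);
  for (size_t k = 0; k < N; ++k) S[k] = as_vec(seqs[k]);
  size_t P = N * (N - 1) / 2;
  NumericVector out(P);
  std::vector<double> M;
  std::vector<int> K;
  size_t p = 0;
  for (size_t i = 0; i + 1 < N; ++i)
    for (size_t j = i + 1; j < N; ++j, ++p)
      out[p] = pair_score(S[i], S[j], D, gap, M, K);
  return out;
}

// scores of one query against every sequence
// [[Rcpp::export]]
NumericVector nw_score_query_cpp(IntegerVector q, List seqs, NumericMatrix D,
                                 double gap) {
  std::vector<int> a(q.begin(), q.end());
  size_t N = seqs.size();
  NumericVector out(N);
  std::vector<double> M;
  std::vector<int> K;
  for (size_t k = 0; k < N; ++k) {
    std::vector<int> b = as_vec(seqs[k]);
    out[k] = pair_score(a, b, D, gap, M, K);
  }
  return out;
}
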