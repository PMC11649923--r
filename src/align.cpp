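#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment (Gotoh three-state DP) with affine gaps.
// Gap of length k costs gap_open + (k - 1) * gap_extend.
// Traceback tie-breaking is fixed for reproducibility: diagonal (match
// state) is preferred over up (gap in b, consuming a) over left (gap in a,
// consuming b), both when choosing the final state and when choosing each
// predecessor.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // state matrices: M diag, X up (consume a), Y left (consume b)
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG_INF));
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[0][j] = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double best_prev = std::max(M[i - 1][j - 1],
                                  std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      M[i][j] = best_prev + s;
      X[i][j] = std::max(M[i - 1][j] + gap_open,
                         std::max(X[i - 1][j] + gap_extend,
                                  Y[i - 1][j] + gap_open));
      Y[i][j] = std::max(M[i][j - 1] + gap_open,
                         std::max(X[i][j - 1] + gap_open,
                                  Y[i][j - 1] + gap_extend));
    }
  }

  double score = std::max(M[n][m], std::max(X[n][m], Y[n][m]));
  // state codes: 0 = M (diagonal), 1 = X (up), 2 = Y (left)
  int state = (M[n][m] >= X[n][m] && M[n][m] >= Y[n][m]) ? 0
              : (X[n][m] >= Y[n][m] ? 1 : 2);

  std::string ga, gb;  // built backwards
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("traceback error in match state");
      ga.push_back(a[i - 1]);
      gb.push_back(b[j - 1]);
      double target = M[i][j] - ((a[i - 1] == b[j - 1]) ? match : mismatch);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[i][j] == target) state = 0;
      else if (X[i][j] == target) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (i == 0) stop("traceback error in up state");
      ga.push_back(a[i - 1]);
      gb.push_back('-');
      double cur = X[i][j];
      --i;
      if (i == 0 && j == 0) break;
      if (M[i][j] + gap_open == cur) state = 0;
      else if (X[i][j] + gap_extend == cur) state = 1;
      else state = 2;
    } else {
      if (j == 0) stop("traceback error in left state");
      ga.push_back('-');
      gb.push_back(b[j - 1]);
      double cur = Y[i][j];
      --j;
      if (i == 0 && j == 0) break;
      if (M[i][j] + gap_open == cur) state = 0;
      else if (X[i][j] + gap_open == cur) state = 1;
      else state = 2;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["aligned_a"] = ga, _["aligned_b"] = gb,
                      _["score"] = score);
}

// Exhaustive-enumeration oracle: walks every monotone alignment path and
// scores it with the same affine gap rule, with no dynamic programming.
// Exponential; intended for sequences of length <= ~10 in tests.
static double enum_best(const std::string &a, const std::string &b,
                        int i, int j, int last, double acc, double match,
                        double mismatch, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (i == n && j == m) return acc;
  double best = NEG_INF;
  if (i < n && j < m) {
    double s = (a[i] == b[j]) ? match : mismatch;
    best = std::max(best, enum_best(a, b, i + 1, j + 1, 0, acc + s, match,
                                    mismatch, gap_open, gap_extend));
  }
  if (i < n) {  // gap in b
    double g = (last == 1) ? gap_extend : gap_open;
    best = std::max(best, enum_best(a, b, i + 1, j, 1, acc + g, match,
                                    mismatch, gap_open, gap_extend));
  }
  if (j < m) {  // gap in a
    double g = (last == 2) ? gap_extend : gap_open;
    best = std::max(best, enum_best(a, b, i, j + 1, 2, acc + g, match,
                                    mismatch, gap_open, gap_extend));
  }
  return best;
}

// [[Rcpp::export(name = ".nw_enumerate_oracle_cpp")]]
double nw_enumerate_oracle_cpp(std::string a, std::string b, double match,
                               double mismatch, double gap_open,
                               double gap_extend) {
  if (a.size() > 10 || b.size() > 10)
    stop("enumeration oracle is limited to sequences of length <= 10");
  return enum_best(a, b, 0, 0, -1, 0.0, match, mismatch, gap_open, gap_extend);
}
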