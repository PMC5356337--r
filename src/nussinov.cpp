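#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted base-pair maximization (Nussinov-style) with a minimum hairpin
// loop of `minLoop` unpaired nucleotides. Pair weights approximate relative
// thermodynamic stability: G:C = 3, A:T(U) = 2, G:T(U) wobble = 1.
// Returns the dot-bracket structure of one optimal structure (deterministic
// traceback: pairing i with the smallest admissible j is preferred) and the
// total weight, reported as a negative pseudo-energy so that "lower is
// better" matches thermodynamic backends.

static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int minLoop = 3) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) {
    char c = toupper(seq[i]);
    if (c == 'U') c = 'T';
    seq[i] = c;
  }
  if (n == 0)
    return List::create(_["structure"] = "", _["energy"] = 0.0);

  // dp[i][j]: best weight on seq[i..j]
  std::vector< std::vector<int> > dp(n, std::vector<int>(n, 0));
  for (int len = minLoop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = dp[i + 1][j]; // i unpaired
      for (int k = i + minLoop + 1; k <= j; ++k) {
        int w = pair_weight(seq[i], seq[k]);
        if (w == 0) continue;
        int left = dp[i + 1][k - 1];
        int right = (k + 1 <= j) ? dp[k + 1][j] : 0;
        int cand = w + left + right;
        if (cand > best) best = cand;
      }
      dp[i][j] = best;
    }
  }

  std::string structure(n, '.');
  // iterative traceback over intervals
  std::vector< std::pair<int,int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < minLoop + 1) continue;
    if (dp[i][j] == dp[i + 1][j]) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + minLoop + 1; k <= j; ++k) {
      int w = pair_weight(seq[i], seq[k]);
      if (w == 0) continue;
      int left = dp[i + 1][k - 1];
      int right = (k + 1 <= j) ? dp[k + 1][j] : 0;
      if (dp[i][j] == w + left + right) {
        structure[i] = '(';
        structure[k] = ')';
        stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }

  return List::create(_["structure"] = structure,
                      _["energy"] = -static_cast<double>(dp[0][n - 1]));
}
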