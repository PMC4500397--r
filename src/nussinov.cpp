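#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Base-pair maximization (Nussinov) for DNA hairpins: Watson-Crick pairs only
// (A:T, G:C; no G:U since the substrate is DNA), minimum hairpin loop length
// min_loop. Returns a 1-based pairing vector (0 = unpaired). The traceback is
// deterministic: at each subproblem, pairing the 5' base is preferred over
// leaving it unpaired, and the most distal admissible partner is taken first,
// which favors contiguous (stacked) stems among co-optimal structures.

static inline bool can_pair(int a, int b) {
  // encoding: A=1, C=2, G=3, T=4
  return (a == 1 && b == 4) || (a == 4 && b == 1) ||
         (a == 2 && b == 3) || (a == 3 && b == 2);
}

// [[Rcpp::export]]
IntegerVector nussinov_cpp(IntegerVector enc, int min_loop) {
  const int n = enc.size();
  IntegerVector partner(n, 0);
  if (n < min_loop + 2) return partner;

  std::vector<std::vector<int>> N(n + 2, std::vector<int>(n + 2, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      int best = N[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (can_pair(enc[i - 1], enc[k - 1])) {
          int v = 1 + N[i + 1][k - 1] + (k < j ? N[k + 1][j] : 0);
          if (v > best) best = v;
        }
      }
      N[i][j] = best;
    }
  }

  // traceback
  std::vector<std::pair<int, int>> stack;
  stack.push_back({1, n});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (N[i][j] == 0) continue;
    bool paired = false;
    for (int k = j; k >= i + min_loop + 1; --k) {
      if (can_pair(enc[i - 1], enc[k - 1])) {
        int v = 1 + N[i + 1][k - 1] + (k < j ? N[k + 1][j] : 0);
        if (v == N[i][j]) {
          partner[i - 1] = k;
          partner[k - 1] = i;
          stack.push_back({i + 1, k - 1});
          if (k < j) stack.push_back({k + 1, j});
          paired = true;
          break;
        }
      }
    }
    if (!paired) stack.push_back({i + 1, j});
  }
  return partner;
}
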