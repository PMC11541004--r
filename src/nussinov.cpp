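#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair maximization over Watson-Crick (A:T, G:C) plus G:T wobble pairs
// with a minimum hairpin loop. DNA alphabet; traceback is deterministic:
// at (i, j) a pairing of i is preferred over leaving i unpaired, and the
// largest admissible partner is taken first.
namespace {

inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

}  // namespace

// [[Rcpp::export]]
List cpp_nussinov(std::string seq, int min_loop) {
  const int n = (int)seq.size();
  std::vector<std::vector<int>> N(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = N[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int v = 1 + (k - i >= 2 ? N[i + 1][k - 1] : 0) +
                (k < j ? N[k + 1][j] : 0);
        if (v > best) best = v;
      }
      N[i][j] = best;
    }
  }
  // deterministic traceback: prefer pairing smallest i, largest partner k
  std::vector<int> pi, pj;
  std::string db(n, '.');
  std::vector<std::pair<int, int>> stack;
  if (n > 0) stack.push_back({0, n - 1});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    bool paired = false;
    for (int k = j; k >= i + min_loop + 1; --k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int v = 1 + (k - i >= 2 ? N[i + 1][k - 1] : 0) +
              (k < j ? N[k + 1][j] : 0);
      if (v == N[i][j]) {
        pi.push_back(i); pj.push_back(k);
        db[i] = '('; db[k] = ')';
        if (k < j) stack.push_back({k + 1, j});
        if (k - i >= 2) stack.push_back({i + 1, k - 1});
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back({i + 1, j});
  }
  int total = (n >= min_loop + 2) ? N[0][n - 1] : 0;
  return List::create(
    _["n_pairs"] = total,
    _["pair_i"] = wrap(pi), _["pair_j"] = wrap(pj),
    _["dotbracket"] = db);
}
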