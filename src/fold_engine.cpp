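#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair maximisation fallback folding engine (Nussinov-style dynamic
// programme with weighted pairs and a minimum hairpin loop of 3 nt).
// Pseudo-energies: G:C -3, A:U -2, G:U -1 "kcal/mol" per pair.  The engine is
// deterministic; ties are broken in favour of (i) pairing i with the
// smallest admissible j, (ii) the leftmost bifurcation point.

static inline double pair_weight(char a, char b) {
  // sequences are normalised to uppercase A/C/G/T upstream
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3.0;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2.0;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1.0;
  return 0.0;
}

static const int MIN_LOOP = 3;

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq) {
  int n = seq.size();
  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);
  // W[i][j]: best weight for subsequence i..j (0-based, inclusive)
  std::vector< std::vector<double> > W(n, std::vector<double>(n, 0.0));
  for (int span = MIN_LOOP + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double best = W[i][j - 1];               // j unpaired
      // j paired with k in [i, j - MIN_LOOP - 1]
      for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
        double w = pair_weight(seq[k], seq[j]);
        if (w <= 0.0) continue;
        double cand = w + (k > i ? W[i][k - 1] : 0.0) +
                      (k + 1 <= j - 1 ? W[k + 1][j - 1] : 0.0);
        if (cand > best) best = cand;
      }
      W[i][j] = best;
    }
  }
  // traceback (iterative, stack of intervals)
  std::string db(n, '.');
  std::vector< std::pair<int,int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i <= MIN_LOOP) continue;
    if (W[i][j] == W[i][j - 1]) {              // j unpaired
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
      double w = pair_weight(seq[k], seq[j]);
      if (w <= 0.0) continue;
      double cand = w + (k > i ? W[i][k - 1] : 0.0) +
                    (k + 1 <= j - 1 ? W[k + 1][j - 1] : 0.0);
      if (cand == W[i][j]) {
        db[k] = '('; db[j] = ')';
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return List::create(_["structure"] = db, _["mfe"] = -W[0][n - 1]);
}
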