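#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Ungapped miRNA target-site scanner.  The miRNA (5'->3') is aligned against
// the reverse of the candidate site window (transcript sense strand), so
// miRNA position i faces site base (end - i + 1).  Penalties per position:
// Watson-Crick 0, G:U wobble `gu`, mismatch `mm`.  Windows are rejected when
// the running score exceeds `max_score` or when miRNA positions 10/11 are not
// strict Watson-Crick pairs (the cleavage-site rule).

static inline int pair_class(char m, char t) {
  // m: miRNA base, t: mRNA (site) base, both DNA alphabet, T == U
  if ((m == 'A' && t == 'T') || (m == 'T' && t == 'A') ||
      (m == 'G' && t == 'C') || (m == 'C' && t == 'G')) return 0; // WC
  if ((m == 'G' && t == 'T') || (m == 'T' && t == 'G')) return 1; // G:U
  return 2;                                                       // mismatch
}

// [[Rcpp::export(name = ".scan_sites_cpp")]]
DataFrame scan_sites_cpp(std::string mirna, std::string transcript,
                         double max_score, double gu, double mm) {
  int L = mirna.size(), n = transcript.size();
  std::vector<int> starts;
  std::vector<double> scores;
  std::vector<std::string> pairings;
  if (L >= 10 && n >= L) {
    for (int s = 0; s + L <= n; ++s) {
      double sc = 0.0;
      std::string pr(L, 'x');
      bool ok = true;
      for (int i = 0; i < L; ++i) {
        // miRNA position i+1 faces transcript position s + L - 1 - i
        int cls = pair_class(mirna[i], transcript[s + L - 1 - i]);
        if ((i == 9 || i == 10) && cls != 0) { ok = false; break; }
        if (cls == 0) pr[i] = '|';
        else if (cls == 1) { pr[i] = 'o'; sc += gu; }
        else { pr[i] = 'x'; sc += mm; }
        if (sc > max_score) { ok = false; break; }
      }
      if (ok) {
        starts.push_back(s + 1);
        scores.push_back(sc);
        pairings.push_back(pr);
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["score"] = scores,
                           _["pairing"] = pairings,
                           _["stringsAsFactors"] = false);
}
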