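// Simplified McCaskill-style partition function over RNA secondary
// structures with per-pair energies only (no loop terms), used to score
// the probability that a target segment is free of intramolecular pairing.
// Structures are non-crossing sets of admissible pairs with a minimum
// hairpin loop of 3 nt and a maximum pair span; admissible pairs are the
// Watson-Crick pairs plus G:U wobbles.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const double RT37 = 0.0019872 * 310.15; // kcal/mol

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    default: return -1; // N or anything else: cannot pair
  }
}

// pair free energies (kcal/mol): GC/CG, AU/UA, GU/UG
static inline double pair_energy(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -3.0; // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2.0; // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -1.0; // G:U
  return 0.0; // not admissible (flagged separately)
}

static inline bool can_pair(int a, int b) {
  if (a < 0 || b < 0) return false;
  return (a + b == 3) || (a == 2 && b == 3) || (a == 3 && b == 2);
}

// partition function over [0, n); forbidden[i] == 1 bars position i from
// pairing.  min loop 3 unpaired nt => j - k >= 4; span constraint
// j - k <= maxspan.
static double partition_Z(const std::vector<int>& code,
                          const std::vector<char>& forbidden,
                          int maxspan) {
  int n = (int)code.size();
  if (n == 0) return 1.0;
  // Q[i][j] stored as flattened (j - i + 1) triangular table
  std::vector<std::vector<double> > Q(n, std::vector<double>(n + 1, 1.0));
  // Q[i][m] = partition function of subsequence starting at i, length m
  // (Q[i][0] = 1)
  std::vector<std::vector<double> > W(n, std::vector<double>(n, 0.0));
  // W[k][j] = exp(-e(k,j)/RT) if pair (k,j) admissible and allowed
  for (int k = 0; k < n; ++k)
    for (int j = k + 4; j < n && j - k <= maxspan; ++j)
      if (!forbidden[k] && !forbidden[j] && can_pair(code[k], code[j]))
        W[k][j] = std::exp(-pair_energy(code[k], code[j]) / RT37);

  for (int m = 1; m <= n; ++m) {       // subsequence length
    for (int i = 0; i + m <= n; ++i) { // start
      int j = i + m - 1;               // inclusive end
      double q = Q[i][m - 1];          // j unpaired
      int kmin = j - maxspan; if (kmin < i) kmin = i;
      for (int k = kmin; k <= j - 4; ++k) {
        if (W[k][j] == 0.0) continue;
        double left = (k > i) ? Q[i][k - i] : 1.0;
        double inner = Q[k + 1][j - k - 1];
        q += left * W[k][j] * inner;
      }
      Q[i][m] = q;
    }
  }
  return Q[0][n];
}

// [[Rcpp::export(name = ".pf_unpaired")]]
double pf_unpaired(std::string seq, int win_start, int win_len,
                   int maxspan) {
  int n = (int)seq.size();
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);
  std::vector<char> forbidden(n, 0);
  double Z = partition_Z(code, forbidden, maxspan);
  for (int i = win_start; i < win_start + win_len; ++i) {
    if (i < 0 || i >= n) stop("window outside sequence");
    forbidden[i] = 1;
  }
  double Zc = partition_Z(code, forbidden, maxspan);
  return Zc / Z;
}
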