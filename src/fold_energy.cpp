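#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Toy nested-structure energy model: GC -3, AU -2, GU -1 kcal/mol,
// minimum hairpin loop of 3 unpaired nucleotides, no pseudoknots.
static inline double pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0;  // sentinel: not a valid pair
}

static double fold_energy_core(const std::string& s, int min_loop) {
  const int n = (int) s.size();
  if (n < min_loop + 2) return 0.0;
  std::vector<double> E((size_t) n * n, 0.0);
  // E[i + n*j]: minimum energy of s[i..j], 0-based inclusive
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E[i + (size_t) n * (j - 1)];  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double e = pair_energy(s[k], s[j]);
        if (e > 0) continue;
        double left = (k > i) ? E[i + (size_t) n * (k - 1)] : 0.0;
        double inner = (k + 1 <= j - 1) ? E[(k + 1) + (size_t) n * (j - 1)]
                                        : 0.0;
        double cand = left + inner + e;
        if (cand < best) best = cand;
      }
      E[i + (size_t) n * j] = best;
    }
  }
  return E[0 + (size_t) n * (n - 1)];
}

// [[Rcpp::export]]
double fold_energy_cpp(std::string seq, int min_loop) {
  return fold_energy_core(seq, min_loop);
}

// Minimum folding energy of every sliding window (1-based starts
// 1, 1+step, ...) of width `window`.
// [[Rcpp::export]]
NumericVector fold_energy_windows_cpp(std::string seq, int window, int step,
                                      int min_loop) {
  const int n = (int) seq.size();
  if (window > n) stop("window exceeds sequence length");
  std::vector<double> out;
  for (int start = 0; start + window <= n; start += step)
    out.push_back(fold_energy_core(seq.substr(start, window), min_loop));
  return wrap(out);
}
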