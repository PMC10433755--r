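#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sparse overlapping k-mer counting over the ACGT alphabet. Each word of
// length k in [kmin, kmax] maps to column offset(k) + base4(word) with
// A=0, C=1, G=2, T=3 and the first character most significant -- i.e.
// columns are ordered by k, then lexicographically, matching the dense
// counterpart's column order. Windows containing any non-ACGT character
// are skipped. Returns 1-based triplets for Matrix::sparseMatrix().

// [[Rcpp::export]]
List kmer_count_triplets(CharacterVector seqs, int kmin, int kmax) {
  const int nk = kmax - kmin + 1;
  std::vector<double> offs(nk + 1, 0.0);
  for (int t = 0; t < nk; ++t) {
    double cols = 1.0;
    for (int j = 0; j < kmin + t; ++j) cols *= 4.0;
    offs[t + 1] = offs[t] + cols;
  }
  std::vector<int> I, J;
  std::vector<double> X;
  std::vector<int> codes;
  std::vector<int> cols;
  for (int s = 0; s < seqs.size(); ++s) {
    const char *p = CHAR(STRING_ELT(seqs, s));
    int n = (int)LENGTH(STRING_ELT(seqs, s));
    codes.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      switch (p[i]) {
      case 'A': case 'a': codes[i] = 0; break;
      case 'C': case 'c': codes[i] = 1; break;
      case 'G': case 'g': codes[i] = 2; break;
      case 'T': case 't': codes[i] = 3; break;
      default: codes[i] = -1;
      }
    }
    cols.clear();
    for (int t = 0; t < nk; ++t) {
      const int k = kmin + t;
      if (n < k) continue;
      const unsigned mask = (1u << (2 * k)) - 1u;
      unsigned code = 0;
      int valid = 0;
      for (int i = 0; i < n; ++i) {
        if (codes[i] < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (unsigned)codes[i]) & mask;
        if (++valid >= k) {
          cols.push_back((int)offs[t] + (int)code);
        }
      }
    }
    std::sort(cols.begin(), cols.end());
    size_t i = 0;
    while (i < cols.size()) {
      size_t j = i;
      while (j < cols.size() && cols[j] == cols[i]) ++j;
      I.push_back(s + 1);
      J.push_back(cols[i] + 1);
      X.push_back((double)(j - i));
      i = j;
    }
  }
  return List::create(_["i"] = wrap(I), _["j"] = wrap(J), _["x"] = wrap(X),
                      _["ncol"] = offs[nk]);
}
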