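#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;  // N or anything else invalidates the window
  }
}

static std::string decode_kmer(uint64_t v, int k) {
  static const char alpha[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = alpha[v & 3ULL];
    v >>= 2;
  }
  return s;
}

// Canonical k-mer counting with 2-bit rolling encoding. The canonical form is
// the lexicographic minimum of a window and its reverse complement, which for
// the A<C<G<T encoding equals the numeric minimum of the two codes. Windows
// containing a non-ACGT character are skipped.
// [[Rcpp::export(name = ".kmer_count_cpp")]]
List kmer_count_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, double> tab;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const int rc_shift = 2 * (k - 1);
  double total = 0.0;

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (const char* c = p; *c; ++c) {
      int b = base_code(*c);
      if (b < 0) {
        valid = 0;
        fwd = rev = 0;
        continue;
      }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << rc_shift);
      if (++valid >= k) {
        tab[fwd < rev ? fwd : rev] += 1.0;
        total += 1.0;
      }
    }
  }

  R_xlen_t n = (R_xlen_t)tab.size();
  CharacterVector kmer(n);
  NumericVector count(n);
  R_xlen_t i = 0;
  for (const auto& kv : tab) {
    kmer[i] = decode_kmer(kv.first, k);
    count[i] = kv.second;
    ++i;
  }
  return List::create(_["kmer"] = kmer, _["count"] = count,
                      _["total"] = total);
}
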