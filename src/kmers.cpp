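#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; k <= 31 fits one uint64_t.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string decode_kmer(uint64_t enc, int k) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'N');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[enc & 3ULL];
    enc >>= 2;
  }
  return s;
}

// Sliding canonical k-mer scan. For every window free of non-ACGT bases the
// forward code and reverse-complement code are maintained in O(1) per shift;
// the canonical form is the numerically smaller code, which for 2-bit
// A<C<G<T encoding equals the lexicographic minimum of strand and revcomp.
template <typename Fn>
static void scan_kmers(const char* s, size_t n, int k, Fn&& emit) {
  if ((int)n < k) return;
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  int valid = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++valid >= k) emit(fwd <= rev ? fwd : rev);
  }
}

// [[Rcpp::export(name = ".count_kmers_cpp")]]
List count_kmers_cpp(CharacterVector seqs, int k) {
  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = std::strlen(s);
    scan_kmers(s, n, k, [&](uint64_t km) { counts[km] += 1; });
  }
  R_xlen_t m = counts.size();
  CharacterVector kmer(m);
  IntegerVector count(m);
  R_xlen_t j = 0;
  for (const auto& kv : counts) {
    kmer[j] = decode_kmer(kv.first, k);
    count[j] = kv.second;
    ++j;
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

static std::unordered_set<uint64_t> encode_set(const CharacterVector& kmers, int k) {
  std::unordered_set<uint64_t> out;
  out.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    uint64_t enc = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base_code(s[j]);
      if (c < 0) { ok = false; break; }
      enc = (enc << 2) | (uint64_t)c;
    }
    if (ok) out.insert(enc);
  }
  return out;
}

// Per sequence: number of canonical k-mers present in set A and in set B.
// Members of A and B are assumed canonical already (length-k ACGT strings).
// [[Rcpp::export(name = ".kmer_hits_cpp")]]
IntegerMatrix kmer_hits_cpp(CharacterVector seqs, int k,
                            CharacterVector setA, CharacterVector setB) {
  std::unordered_set<uint64_t> a = encode_set(setA, k);
  std::unordered_set<uint64_t> b = encode_set(setB, k);
  R_xlen_t n = seqs.size();
  IntegerMatrix hits(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t len = std::strlen(s);
    int na = 0, nb = 0;
    scan_kmers(s, len, k, [&](uint64_t km) {
      if (a.count(km)) ++na;
      if (b.count(km)) ++nb;
    });
    hits(i, 0) = na;
    hits(i, 1) = nb;
  }
  colnames(hits) = CharacterVector::create("n_a", "n_b");
  return hits;
}
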