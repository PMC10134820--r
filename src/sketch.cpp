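// MinHash sketching backend.
//
// k-mers over {A,C,G,T} are packed 2 bits per base (A=0, C=1, G=2, T=3);
// packing preserves lexicographic order, so min(packed fwd, packed rc) is
// the canonical (lexicographically smallest) strand. Windows containing any
// other character (N, IUPAC codes, lower case is accepted and upcased) are
// skipped. The hash is a seeded splitmix64-style finalizer truncated to the
// top 53 bits so every hash value is exactly representable in an R double.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cctype>
using namespace Rcpp;

static const uint64_t HASH_SEED = 42ULL;  // fixed, documented sketch seed

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t hash_kmer(uint64_t canon, uint64_t seed) {
  return mix64(canon ^ mix64(seed)) >> 11;  // 53-bit value
}

static inline int base_code(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// Distinct canonical k-mer hashes of a set of contig sequences, sorted
// ascending, truncated to the smallest s (s <= 0 keeps all).
// [[Rcpp::export]]
NumericVector cpp_sketch_hashes(CharacterVector seqs, int k, int s) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::vector<uint64_t> hashes;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *seq = CHAR(STRING_ELT(seqs, i));
    uint64_t fwd = 0, rc = 0;
    int run = 0;  // length of current valid-base run
    for (const char *p = seq; *p; ++p) {
      int code = base_code(*p);
      if (code < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | static_cast<uint64_t>(code)) & mask;
      rc = (rc >> 2) | (static_cast<uint64_t>(3 - code) << shift);
      if (++run >= k) {
        uint64_t canon = fwd < rc ? fwd : rc;
        hashes.push_back(hash_kmer(canon, HASH_SEED));
      }
    }
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  size_t keep = hashes.size();
  if (s > 0 && static_cast<size_t>(s) < keep) keep = static_cast<size_t>(s);
  NumericVector out(keep);
  for (size_t i = 0; i < keep; ++i) out[i] = static_cast<double>(hashes[i]);
  return out;
}

// Stable 53-bit hash of a numeric vector (values taken as integral doubles).
// Used for fingerprint invariants and config digests.
// [[Rcpp::export]]
double cpp_hash_numvec(NumericVector v, double seed = 0) {
  uint64_t h = mix64(static_cast<uint64_t>(seed) ^ HASH_SEED);
  for (R_xlen_t i = 0; i < v.size(); ++i) {
    uint64_t x = static_cast<uint64_t>(static_cast<int64_t>(v[i]));
    h = mix64(h ^ x);
  }
  return static_cast<double>(h >> 11);
}

// Stable 53-bit hash of a string.
// [[Rcpp::export]]
double cpp_hash_string(std::string x, double seed = 0) {
  uint64_t h = mix64(static_cast<uint64_t>(seed) ^ HASH_SEED);
  for (size_t i = 0; i < x.size(); ++i) {
    h = mix64(h ^ static_cast<uint64_t>(static_cast<unsigned char>(x[i])));
  }
  return static_cast<double>(h >> 11);
}
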