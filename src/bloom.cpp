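#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// 64-bit FNV-1a over the k-mer bytes. Two different offset bases give the
// two hashes combined by double hashing: index_i = (h1 + i*h2) mod m.
static inline uint64_t fnv1a64(const char *s, uint64_t basis) {
  const uint64_t prime = 1099511628211ULL;
  uint64_t h = basis;
  for (const char *p = s; *p; ++p) {
    h ^= (uint64_t)(unsigned char)(*p);
    h *= prime;
  }
  return h;
}

static const uint64_t BASIS1 = 14695981039346656037ULL;
static const uint64_t BASIS2 = 0x9E3779B97F4A7C15ULL;

// [[Rcpp::export]]
RawVector bloom_bits_alloc(double m_bits) {
  R_xlen_t nbytes = (R_xlen_t)((m_bits + 7) / 8);
  RawVector bits(nbytes); // zero-initialised
  return bits;
}

// Inserts every k-mer; 'bits' is modified in place (callers create it
// immediately beforehand, so the vector is never aliased).
// [[Rcpp::export]]
void bloom_insert_cpp(RawVector bits, double m_bits, int num_hashes,
                      CharacterVector kmers) {
  uint64_t m = (uint64_t)m_bits;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    uint64_t h1 = fnv1a64(s, BASIS1);
    uint64_t h2 = fnv1a64(s, BASIS2) | 1ULL;
    for (int j = 0; j < num_hashes; ++j) {
      uint64_t idx = (h1 + (uint64_t)j * h2) % m;
      bits[idx >> 3] |= (Rbyte)(1u << (idx & 7u));
    }
  }
}

// [[Rcpp::export]]
LogicalVector bloom_query_cpp(RawVector bits, double m_bits, int num_hashes,
                              CharacterVector kmers) {
  uint64_t m = (uint64_t)m_bits;
  R_xlen_t n = kmers.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    uint64_t h1 = fnv1a64(s, BASIS1);
    uint64_t h2 = fnv1a64(s, BASIS2) | 1ULL;
    bool hit = true;
    for (int j = 0; j < num_hashes && hit; ++j) {
      uint64_t idx = (h1 + (uint64_t)j * h2) % m;
      hit = (bits[idx >> 3] >> (idx & 7u)) & 1u;
    }
    out[i] = hit;
  }
  return out;
}
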