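// MurmurHash3 x86_32 (public-domain algorithm by Austin Appleby).
// Used for the hashing trick: allele keys -> columns.  The hash must be
// identical across platforms and runs, which rules out R's serialization
// hashes; 32-bit output is interpreted as a *signed* integer to match the
// abs(hash(s)) %% k column rule.
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static inline uint32_t rotl32(uint32_t x, int8_t r) {
  return (x << r) | (x >> (32 - r));
}

static inline uint32_t fmix32(uint32_t h) {
  h ^= h >> 16;
  h *= 0x85ebca6bU;
  h ^= h >> 13;
  h *= 0xc2b2ae35U;
  h ^= h >> 16;
  return h;
}

static uint32_t murmur3_x86_32(const unsigned char *data, int len, uint32_t seed) {
  const int nblocks = len / 4;
  uint32_t h1 = seed;
  const uint32_t c1 = 0xcc9e2d51U;
  const uint32_t c2 = 0x1b873593U;

  for (int i = 0; i < nblocks; i++) {
    uint32_t k1 = (uint32_t)data[i * 4] |
                  ((uint32_t)data[i * 4 + 1] << 8) |
                  ((uint32_t)data[i * 4 + 2] << 16) |
                  ((uint32_t)data[i * 4 + 3] << 24);
    k1 *= c1;
    k1 = rotl32(k1, 15);
    k1 *= c2;
    h1 ^= k1;
    h1 = rotl32(h1, 13);
    h1 = h1 * 5 + 0xe6546b64U;
  }

  const unsigned char *tail = data + nblocks * 4;
  uint32_t k1 = 0;
  switch (len & 3) {
  case 3: k1 ^= (uint32_t)tail[2] << 16; // fall through
  case 2: k1 ^= (uint32_t)tail[1] << 8;  // fall through
  case 1: k1 ^= (uint32_t)tail[0];
    k1 *= c1;
    k1 = rotl32(k1, 15);
    k1 *= c2;
    h1 ^= k1;
  }

  h1 ^= (uint32_t)len;
  return fmix32(h1);
}

//' Signed 32-bit MurmurHash3 of character strings
//'
//' @param keys character vector of keys to hash
//' @param seed hash seed (non-negative integer)
//' @return integer vector of signed 32-bit hash values
//' @keywords internal
// [[Rcpp::export]]
IntegerVector murmur32(CharacterVector keys, int seed = 0) {
  R_xlen_t n = keys.size();
  IntegerVector out(n);
  uint32_t s = (uint32_t)seed;
  for (R_xlen_t i = 0; i < n; i++) {
    if (CharacterVector::is_na(keys[i])) {
      out[i] = NA_INTEGER;
      continue;
    }
    const char *str = CHAR(STRING_ELT(keys, i));
    int len = (int)LENGTH(STRING_ELT(keys, i));
    uint32_t h = murmur3_x86_32((const unsigned char *)str, len, s);
    out[i] = (int32_t)h;
  }
  return out;
}

//' Absolute value of the signed 32-bit MurmurHash3, in exact double arithmetic
//'
//' abs() is taken in 64-bit integer arithmetic so that the INT32_MIN case
//' (whose absolute value is not representable in 32 bits) is well defined;
//' all possible results (<= 2^31) are exactly representable as doubles.
//'
//' @param keys character vector of keys to hash
//' @param seed hash seed (non-negative integer)
//' @return numeric vector of abs(signed 32-bit hash) values
//' @keywords internal
// [[Rcpp::export]]
NumericVector murmur32_abs(CharacterVector keys, int seed = 0) {
  R_xlen_t n = keys.size();
  NumericVector out(n);
  uint32_t s = (uint32_t)seed;
  for (R_xlen_t i = 0; i < n; i++) {
    if (CharacterVector::is_na(keys[i])) {
      out[i] = NA_REAL;
      continue;
    }
    const char *str = CHAR(STRING_ELT(keys, i));
    int len = (int)LENGTH(STRING_ELT(keys, i));
    int64_t h = (int64_t)(int32_t)murmur3_x86_32((const unsigned char *)str, len, s);
    out[i] = (double)(h < 0 ? -h : h);
  }
  return out;
}
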