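# Independent pure-R reimplementation of MurmurHash3 x86_32, used as an
# oracle for the compiled hash.  All 32-bit arithmetic is emulated in
# doubles (exact up to 2^53) with 16-bit splits for multiplication and XOR.

.mul32 <- function(a, b) {
  a_lo <- a %% 65536
  a_hi <- (a - a_lo) / 65536
  (((a_hi * b) %% 65536) * 65536 + a_lo * b) %% 4294967296
}

.xor32 <- function(a, b) {
  a_lo <- a %% 65536; b_lo <- b %% 65536
  a_hi <- (a - a_lo) / 65536; b_hi <- (b - b_lo) / 65536
  bitwXor(a_hi, b_hi) * 65536 + bitwXor(a_lo, b_lo)
}

.rotl32 <- function(x, r) {
  ((x * 2^r) %% 4294967296) + floor(x / 2^(32 - r))
}

.shr32 <- function(x, s) floor(x / 2^s)

.fmix32 <- function(h) {
  h <- .xor32(h, .shr32(h, 16))
  h <- .mul32(h, 2246822507)   # 0x85ebca6b
  h <- .xor32(h, .shr32(h, 13))
  h <- .mul32(h, 3266489909)   # 0xc2b2ae35
  .xor32(h, .shr32(h, 16))
}

# signed 32-bit MurmurHash3 of a single ASCII string
r_murmur32 <- function(s, seed = 0) {
  bytes <- utf8ToInt(s)
  len <- length(bytes)
  nblocks <- len %/% 4
  h1 <- seed %% 4294967296
  c1 <- 3432918353  # 0xcc9e2d51
  c2 <- 461845907   # 0x1b873593
  for (i in seq_len(nblocks)) {
    b <- bytes[(4 * i - 3):(4 * i)]
    k1 <- b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
    k1 <- .mul32(k1, c1)
    k1 <- .rotl32(k1, 15)
    k1 <- .mul32(k1, c2)
    h1 <- .xor32(h1, k1)
    h1 <- .rotl32(h1, 13)
    h1 <- (h1 * 5 + 3864292196) %% 4294967296  # 0xe6546b64
  }
  tail_len <- len %% 4
  if (tail_len > 0) {
    tb <- bytes[(nblocks * 4 + 1):len]
    k1 <- sum(tb * 256^(seq_along(tb) - 1))
    k1 <- .mul32(k1, c1)
    k1 <- .rotl32(k1, 15)
    k1 <- .mul32(k1, c2)
    h1 <- .xor32(h1, k1)
  }
  h1 <- .xor32(h1, len)
  h1 <- .fmix32(h1)
  if (h1 >= 2147483648) h1 - 4294967296 else h1
}

r_hash_column <- function(key, k, seed = 0) {
  abs(r_murmur32(key, seed)) %% k
}
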