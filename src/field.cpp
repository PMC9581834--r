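// Exact modular arithmetic for prime fields up to 128 bits.
//
// Field elements cross the R boundary as lowercase minimal hex strings;
// internally they are 256-bit fixed-width integers (4 x uint64 limbs) so
// that a full 128x128-bit product never overflows.  Reduction is binary
// shift-subtract: simple, exact, and fast enough for protocol work where
// the per-element cost is dominated by R-level orchestration anyway.

#include <Rcpp.h>
#include <cstdint>
#include <string>

using namespace Rcpp;

typedef uint64_t u64;
typedef unsigned __int128 u128;

struct U256 {
  u64 w[4];
};

static inline U256 zero256() {
  U256 r;
  r.w[0] = r.w[1] = r.w[2] = r.w[3] = 0;
  return r;
}

static inline bool is_zero256(const U256 &a) {
  return (a.w[0] | a.w[1] | a.w[2] | a.w[3]) == 0;
}

static inline int cmp256(const U256 &a, const U256 &b) {
  for (int i = 3; i >= 0; --i) {
    if (a.w[i] < b.w[i]) return -1;
    if (a.w[i] > b.w[i]) return 1;
  }
  return 0;
}

static inline U256 add256(const U256 &a, const U256 &b) {
  U256 r;
  u128 c = 0;
  for (int i = 0; i < 4; ++i) {
    u128 s = (u128)a.w[i] + b.w[i] + c;
    r.w[i] = (u64)s;
    c = s >> 64;
  }
  return r;
}

// assumes a >= b
static inline U256 sub256(const U256 &a, const U256 &b) {
  U256 r;
  u64 borrow = 0;
  for (int i = 0; i < 4; ++i) {
    u128 rhs = (u128)b.w[i] + borrow;
    u128 lhs = (u128)a.w[i];
    r.w[i] = (u64)(lhs - rhs);
    borrow = lhs < rhs ? 1 : 0;
  }
  return r;
}

static inline int bits256(const U256 &a) {
  for (int i = 3; i >= 0; --i) {
    if (a.w[i]) {
      int b = 0;
      u64 v = a.w[i];
      while (v) { ++b; v >>= 1; }
      return 64 * i + b;
    }
  }
  return 0;
}

static inline U256 shl256(const U256 &a, int k) {
  U256 r = zero256();
  int wo = k / 64, bo = k % 64;
  for (int i = 3; i >= 0; --i) {
    int j = i - wo;
    if (j < 0) continue;
    u64 v = a.w[j] << bo;
    if (bo && j > 0) v |= a.w[j - 1] >> (64 - bo);
    r.w[i] = v;
  }
  return r;
}

static inline U256 shr1(const U256 &a) {
  U256 r;
  for (int i = 0; i < 4; ++i) {
    r.w[i] = a.w[i] >> 1;
    if (i < 3) r.w[i] |= a.w[i + 1] << 63;
  }
  return r;
}

static U256 mod256(U256 x, const U256 &p) {
  if (cmp256(x, p) < 0) return x;
  int sh = bits256(x) - bits256(p);
  U256 t = shl256(p, sh);
  for (int i = sh; i >= 0; --i) {
    if (cmp256(x, t) >= 0) x = sub256(x, t);
    t = shr1(t);
  }
  return x;
}

// full product of two values < 2^128
static U256 mul128(const U256 &a, const U256 &b) {
  u64 a0 = a.w[0], a1 = a.w[1], b0 = b.w[0], b1 = b.w[1];
  u128 p00 = (u128)a0 * b0;
  u128 p01 = (u128)a0 * b1;
  u128 p10 = (u128)a1 * b0;
  u128 p11 = (u128)a1 * b1;
  U256 r = zero256();
  r.w[0] = (u64)p00;
  u128 mid = (p00 >> 64);
  mid += (u64)p01;
  mid += (u64)p10;
  r.w[1] = (u64)mid;
  u128 hi = (mid >> 64) + (p01 >> 64) + (p10 >> 64) + (u64)p11;
  r.w[2] = (u64)hi;
  r.w[3] = (u64)(hi >> 64) + (u64)(p11 >> 64);
  return r;
}

static inline U256 addmod(const U256 &a, const U256 &b, const U256 &p) {
  U256 s = add256(a, b);
  if (cmp256(s, p) >= 0) s = sub256(s, p);
  return s;
}

static inline U256 submod(const U256 &a, const U256 &b, const U256 &p) {
  if (cmp256(a, b) >= 0) return sub256(a, b);
  return sub256(add256(a, p), b);
}

static inline U256 mulmod(const U256 &a, const U256 &b, const U256 &p) {
  return mod256(mul128(a, b), p);
}

static U256 powmod(const U256 &a, const U256 &e, const U256 &p) {
  U256 base = mod256(a, p);
  U256 acc = zero256();
  acc.w[0] = 1;
  acc = mod256(acc, p); // p == 1 guard
  int nb = bits256(e);
  for (int i = 0; i < nb; ++i) {
    if ((e.w[i / 64] >> (i % 64)) & 1) acc = mulmod(acc, base, p);
    base = mulmod(base, base, p);
  }
  return acc;
}

static int hexval(char c) {
  if (c >= '0' && c <= '9') return c - '0';
  if (c >= 'a' && c <= 'f') return c - 'a' + 10;
  if (c >= 'A' && c <= 'F') return c - 'A' + 10;
  return -1;
}

static U256 parse_hex(const std::string &s) {
  if (s.empty()) stop("empty hex string");
  size_t start = 0;
  if (s.size() > 2 && s[0] == '0' && (s[1] == 'x' || s[1] == 'X')) start = 2;
  if (s.size() - start > 64) stop("hex value exceeds 256 bits: '%s'", s.c_str());
  if (s.size() == start) stop("empty hex string");
  U256 r = zero256();
  for (size_t i = start; i < s.size(); ++i) {
    int v = hexval(s[i]);
    if (v < 0) stop("invalid hex character in '%s'", s.c_str());
    // r = r*16 + v
    r = shl256(r, 4);
    r.w[0] |= (u64)v;
  }
  return r;
}

static std::string to_hex(const U256 &a) {
  static const char *digits = "0123456789abcdef";
  int nb = bits256(a);
  if (nb == 0) return "0";
  int nd = (nb + 3) / 4;
  std::string s(nd, '0');
  for (int i = 0; i < nd; ++i) {
    int shift = 4 * (nd - 1 - i);
    u64 nib = (a.w[shift / 64] >> (shift % 64)) & 0xF;
    s[i] = digits[nib];
  }
  return s;
}

static U256 from_u64(u64 v) {
  U256 r = zero256();
  r.w[0] = v;
  return r;
}

static U256 parse_modulus(const std::string &p_hex) {
  U256 p = parse_hex(p_hex);
  if (is_zero256(p)) stop("modulus must be positive");
  if (bits256(p) > 128) stop("modulus exceeds 128 bits");
  return p;
}

// canonical lowercase minimal hex (no reduction)
// [[Rcpp::export]]
CharacterVector hex_canon_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = to_hex(parse_hex(CHAR(STRING_ELT(x, i))));
  return out;
}

// ---------------------------------------------------------------------------
// vectorised field ops (x, y recycled to common length)

static inline const char *elt(const CharacterVector &v, R_xlen_t i) {
  return CHAR(STRING_ELT(v, i % v.size()));
}

// [[Rcpp::export]]
CharacterVector fp_add_cpp(CharacterVector x, CharacterVector y, std::string p_hex) {
  U256 p = parse_modulus(p_hex);
  R_xlen_t n = std::max(x.size(), y.size());
  if (x.size() == 0 || y.size() == 0) return CharacterVector(0);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    U256 a = mod256(parse_hex(elt(x, i)), p);
    U256 b = mod256(parse_hex(elt(y, i)), p);
    out[i] = to_hex(addmod(a, b, p));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fp_sub_cpp(CharacterVector x, CharacterVector y, std::string p_hex) {
  U256 p = parse_modulus(p_hex);
  R_xlen_t n = std::max(x.size(), y.size());
  if (x.size() == 0 || y.size() == 0) return CharacterVector(0);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    U256 a = mod256(parse_hex(elt(x, i)), p);
    U256 b = mod256(parse_hex(elt(y, i)), p);
    out[i] = to_hex(submod(a, b, p));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fp_mul_cpp(CharacterVector x, CharacterVector y, std::string p_hex) {
  U256 p = parse_modulus(p_hex);
  R_xlen_t n = std::max(x.size(), y.size());
  if (x.size() == 0 || y.size() == 0) return CharacterVector(0);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    U256 a = mod256(parse_hex(elt(x, i)), p);
    U256 b = mod256(parse_hex(elt(y, i)), p);
    out[i] = to_hex(mulmod(a, b, p));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fp_neg_cpp(CharacterVector x, std::string p_hex) {
  U256 p = parse_modulus(p_hex);
  R_xlen_t n = x.size();
  CharacterVector out(n);
  U256 z = zero256();
  for (R_xlen_t i = 0; i < n; ++i) {
    U256 a = mod256(parse_hex(elt(x, i)), p);
    out[i] = to_hex(submod(z, a, p));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fp_pow_cpp(CharacterVector x, CharacterVector e, std::string p_hex) {
  U256 p = parse_modulus(p_hex);
  R_xlen_t n = std::max(x.size(), e.size());
  if (x.size() == 0 || e.size() == 0) return CharacterVector(0);
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    U256 a = mod256(parse_hex(elt(x, i)), p);
    U256 ee = parse_hex(elt(e, i));
    out[i] = to_hex(powmod(a, ee, p));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fp_inv_cpp(CharacterVector x, std::string p_hex) {
  U256 p = parse_modulus(p_hex);
  U256 e = sub256(p, from_u64(2)); // Fermat: x^(p-2) for prime p
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    U256 a = mod256(parse_hex(elt(x, i)), p);
    if (is_zero256(a)) stop("cannot invert zero");
    out[i] = to_hex(powmod(a, e, p));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fp_sum_cpp(CharacterVector x, std::string p_hex) {
  U256 p = parse_modulus(p_hex);
  U256 acc = zero256();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    acc = addmod(acc, mod256(parse_hex(elt(x, i)), p), p);
  return CharacterVector::create(to_hex(acc));
}

// column sums of the logical groups in `grp` (1-based, length == length(x))
// [[Rcpp::export]]
CharacterVector fp_group_sum_cpp(CharacterVector x, IntegerVector grp, int ngroups,
                                 std::string p_hex) {
  if (x.size() != grp.size()) stop("group index length mismatch");
  U256 p = parse_modulus(p_hex);
  std::vector<U256> acc(ngroups, zero256());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    int g = grp[i];
    if (g < 1 || g > ngroups) stop("group index out of range");
    acc[g - 1] = addmod(acc[g - 1], mod256(parse_hex(elt(x, i)), p), p);
  }
  CharacterVector out(ngroups);
  for (int g = 0; g < ngroups; ++g) out[g] = to_hex(acc[g]);
  return out;
}

// ---------------------------------------------------------------------------
// integer <-> field element conversion (doubles are exact below 2^53)

// [[Rcpp::export]]
CharacterVector fp_from_num_cpp(NumericVector v, std::string p_hex) {
  U256 p = parse_modulus(p_hex);
  R_xlen_t n = v.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double d = v[i];
    if (!R_finite(d) || d != std::floor(d)) stop("value must be an integer");
    if (std::abs(d) > 9007199254740992.0) stop("integer magnitude exceeds 2^53");
    bool neg = d < 0;
    U256 a = from_u64((u64)std::llabs((long long)d));
    a = mod256(a, p);
    if (neg) a = submod(zero256(), a, p);
    out[i] = to_hex(a);
  }
  return out;
}

// centered = TRUE decodes via the symmetric lift in (-(p-1)/2, (p-1)/2]
// [[Rcpp::export]]
NumericVector fp_to_num_cpp(CharacterVector x, std::string p_hex, bool centered) {
  U256 p = parse_modulus(p_hex);
  U256 half = shr1(p); // floor((p-1)/2) for odd p
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    U256 a = mod256(parse_hex(elt(x, i)), p);
    bool neg = false;
    if (centered && cmp256(a, half) > 0) {
      a = sub256(p, a);
      neg = true;
    }
    if (bits256(a) > 53) stop("field element too large for exact numeric decode");
    double d = (double)a.w[0];
    out[i] = neg ? -d : d;
  }
  return out;
}

// low `nbits` bits of each element; matrix nbits x k, row i+1 = bit i
// [[Rcpp::export]]
IntegerMatrix fp_bits_cpp(CharacterVector x, int nbits) {
  if (nbits < 1 || nbits > 256) stop("nbits out of range");
  IntegerMatrix out(nbits, x.size());
  for (R_xlen_t j = 0; j < x.size(); ++j) {
    U256 a = parse_hex(elt(x, j));
    for (int i = 0; i < nbits; ++i)
      out(i, j) = (int)((a.w[i / 64] >> (i % 64)) & 1);
  }
  return out;
}

// ---------------------------------------------------------------------------
// fixed-width big-endian serialization

// [[Rcpp::export]]
RawVector fp_to_raw_cpp(CharacterVector x, int width) {
  if (width < 1 || width > 32) stop("element width out of range");
  RawVector out(x.size() * (R_xlen_t)width);
  for (R_xlen_t j = 0; j < x.size(); ++j) {
    U256 a = parse_hex(elt(x, j));
    if (bits256(a) > 8 * width) stop("element does not fit serialization width");
    for (int b = 0; b < width; ++b) {
      int shift = 8 * (width - 1 - b);
      out[j * width + b] = (Rbyte)((a.w[shift / 64] >> (shift % 64)) & 0xFF);
    }
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector fp_from_raw_cpp(RawVector bytes, int width) {
  if (width < 1 || width > 32) stop("element width out of range");
  if (bytes.size() % width != 0) stop("byte stream length is not a multiple of width");
  R_xlen_t n = bytes.size() / width;
  CharacterVector out(n);
  for (R_xlen_t j = 0; j < n; ++j) {
    U256 a = zero256();
    for (int b = 0; b < width; ++b) {
      a = shl256(a, 8);
      a.w[0] |= (u64)bytes[j * width + b];
    }
    out[j] = to_hex(a);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Miller-Rabin probable-prime test (fixed bases; error < 4^-13 per base set)

// [[Rcpp::export]]
bool fp_is_prime_cpp(std::string p_hex) {
  U256 n = parse_hex(p_hex);
  if (bits256(n) > 128) stop("primality check limited to 128 bits");
  if (cmp256(n, from_u64(2)) < 0) return false;
  static const u64 small[] = {2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41};
  for (u64 q : small) {
    U256 Q = from_u64(q);
    if (cmp256(n, Q) == 0) return true;
    if (is_zero256(mod256(n, Q))) return false;
  }
  U256 one = from_u64(1);
  U256 nm1 = sub256(n, one);
  U256 d = nm1;
  int s = 0;
  while (!(d.w[0] & 1)) { d = shr1(d); ++s; }
  for (u64 a : small) {
    U256 x = powmod(from_u64(a), d, n);
    if (cmp256(x, one) == 0 || cmp256(x, nm1) == 0) continue;
    bool composite = true;
    for (int r = 1; r < s; ++r) {
      x = mulmod(x, x, n);
      if (cmp256(x, nm1) == 0) { composite = false; break; }
    }
    if (composite) return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// deterministic per-actor generator: xoshiro256** seeded via splitmix64

struct XoRng {
  u64 s[4];
};

static inline u64 rotl64(u64 x, int k) { return (x << k) | (x >> (64 - k)); }

static u64 splitmix64(u64 &x) {
  x += 0x9E3779B97F4A7C15ULL;
  u64 z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static u64 xo_next(XoRng &g) {
  u64 result = rotl64(g.s[1] * 5, 7) * 9;
  u64 t = g.s[1] << 17;
  g.s[2] ^= g.s[0];
  g.s[3] ^= g.s[1];
  g.s[1] ^= g.s[2];
  g.s[0] ^= g.s[3];
  g.s[2] ^= t;
  g.s[3] = rotl64(g.s[3], 45);
  return result;
}

// [[Rcpp::export]]
SEXP rng_new_cpp(double seed, std::string actor) {
  u64 x = (u64)(long long)seed;
  // fold the actor tag in so dealer/party/client streams differ per seed
  for (char c : actor) x = (x ^ (u64)(unsigned char)c) * 0x100000001B3ULL;
  XoRng *g = new XoRng();
  for (int i = 0; i < 4; ++i) g->s[i] = splitmix64(x);
  if (!(g->s[0] | g->s[1] | g->s[2] | g->s[3])) g->s[0] = 1;
  XPtr<XoRng> ptr(g, true);
  return ptr;
}

// uniform draws in [0, bound) by rejection sampling on bitlength(bound) bits
// [[Rcpp::export]]
CharacterVector rng_below_cpp(SEXP rng, int k, std::string bound_hex) {
  XPtr<XoRng> g(rng);
  U256 bound = parse_hex(bound_hex);
  if (is_zero256(bound)) stop("bound must be positive");
  int nb = bits256(bound);
  int nw = (nb + 63) / 64;
  u64 topmask = (nb % 64) ? ((1ULL << (nb % 64)) - 1) : ~0ULL;
  CharacterVector out(k);
  for (int j = 0; j < k; ++j) {
    U256 cand;
    do {
      cand = zero256();
      for (int i = 0; i < nw; ++i) cand.w[i] = xo_next(*g);
      cand.w[nw - 1] &= topmask;
      for (int i = nw; i < 4; ++i) cand.w[i] = 0;
    } while (cmp256(cand, bound) >= 0);
    out[j] = to_hex(cand);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector rng_bits_cpp(SEXP rng, int k) {
  XPtr<XoRng> g(rng);
  IntegerVector out(k);
  for (int j = 0; j < k; ++j) out[j] = (int)(xo_next(*g) & 1);
  return out;
}

// [[Rcpp::export]]
NumericVector rng_unit_cpp(SEXP rng, int k) {
  XPtr<XoRng> g(rng);
  NumericVector out(k);
  for (int j = 0; j < k; ++j)
    out[j] = (double)(xo_next(*g) >> 11) * (1.0 / 9007199254740992.0);
  return out;
}
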