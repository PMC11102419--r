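// Exact arbitrary-precision rational arithmetic.
//
// Rationals cross the R/C++ boundary as canonical strings "n" or "n/d"
// (d > 0, gcd(n, d) = 1).  All arithmetic is exact; magnitudes are
// little-endian vectors of 32-bit limbs.  Reversal constructions can
// produce numerators/denominators of a few hundred bits, which doubles
// cannot represent, hence this kernel.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

typedef std::vector<uint32_t> Mag; // little-endian, no leading zero limbs

static void trim(Mag &a) {
  while (!a.empty() && a.back() == 0) a.pop_back();
}

static int cmp_mag(const Mag &a, const Mag &b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (size_t i = a.size(); i-- > 0;) {
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  }
  return 0;
}

static Mag add_mag(const Mag &a, const Mag &b) {
  Mag r;
  r.reserve(std::max(a.size(), b.size()) + 1);
  uint64_t carry = 0;
  for (size_t i = 0; i < std::max(a.size(), b.size()); ++i) {
    uint64_t s = carry;
    if (i < a.size()) s += a[i];
    if (i < b.size()) s += b[i];
    r.push_back((uint32_t)(s & 0xffffffffu));
    carry = s >> 32;
  }
  if (carry) r.push_back((uint32_t)carry);
  return r;
}

// requires a >= b
static Mag sub_mag(const Mag &a, const Mag &b) {
  Mag r;
  r.reserve(a.size());
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t s = (int64_t)a[i] - borrow - (i < b.size() ? (int64_t)b[i] : 0);
    if (s < 0) { s += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
    r.push_back((uint32_t)s);
  }
  trim(r);
  return r;
}

static Mag mul_mag(const Mag &a, const Mag &b) {
  if (a.empty() || b.empty()) return Mag();
  Mag r(a.size() + b.size(), 0);
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t carry = 0;
    uint64_t ai = a[i];
    for (size_t j = 0; j < b.size(); ++j) {
      uint64_t s = (uint64_t)r[i + j] + ai * b[j] + carry;
      r[i + j] = (uint32_t)(s & 0xffffffffu);
      carry = s >> 32;
    }
    size_t k = i + b.size();
    while (carry) {
      uint64_t s = (uint64_t)r[k] + carry;
      r[k] = (uint32_t)(s & 0xffffffffu);
      carry = s >> 32;
      ++k;
    }
  }
  trim(r);
  return r;
}

static Mag mul_small(const Mag &a, uint32_t m) {
  Mag r;
  r.reserve(a.size() + 1);
  uint64_t carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t s = (uint64_t)a[i] * m + carry;
    r.push_back((uint32_t)(s & 0xffffffffu));
    carry = s >> 32;
  }
  if (carry) r.push_back((uint32_t)carry);
  trim(r);
  return r;
}

static Mag add_small(const Mag &a, uint32_t m) {
  Mag b;
  if (m) b.push_back(m);
  return add_mag(a, b);
}

// divide by single limb, returns quotient, sets rem
static Mag div_small(const Mag &a, uint32_t m, uint32_t &rem) {
  Mag q(a.size(), 0);
  uint64_t r = 0;
  for (size_t i = a.size(); i-- > 0;) {
    uint64_t cur = (r << 32) | a[i];
    q[i] = (uint32_t)(cur / m);
    r = cur % m;
  }
  rem = (uint32_t)r;
  trim(q);
  return q;
}

static size_t bit_length(const Mag &a) {
  if (a.empty()) return 0;
  uint32_t top = a.back();
  size_t n = (a.size() - 1) * 32;
  while (top) { ++n; top >>= 1; }
  return n;
}

static bool get_bit(const Mag &a, size_t i) {
  size_t w = i / 32, b = i % 32;
  if (w >= a.size()) return false;
  return (a[w] >> b) & 1u;
}

static void set_bit(Mag &a, size_t i) {
  size_t w = i / 32, b = i % 32;
  if (w >= a.size()) a.resize(w + 1, 0);
  a[w] |= (1u << b);
}

// in-place r = r*2 + bit  (shift left one bit, OR in bit)
static void shl1_or(Mag &r, bool bit) {
  uint32_t carry = bit ? 1u : 0u;
  for (size_t i = 0; i < r.size(); ++i) {
    uint32_t nc = r[i] >> 31;
    r[i] = (r[i] << 1) | carry;
    carry = nc;
  }
  if (carry) r.push_back(carry);
}

// schoolbook binary long division: a = q*b + r, 0 <= r < b
static void divmod_mag(const Mag &a, const Mag &b, Mag &q, Mag &r) {
  if (b.empty()) stop("division by zero");
  q.clear(); r.clear();
  if (cmp_mag(a, b) < 0) { r = a; return; }
  size_t nb = bit_length(a);
  for (size_t i = nb; i-- > 0;) {
    shl1_or(r, get_bit(a, i));
    if (cmp_mag(r, b) >= 0) {
      r = sub_mag(r, b);
      set_bit(q, i);
    }
  }
  trim(q); trim(r);
}

static void shr1(Mag &a) {
  for (size_t i = 0; i < a.size(); ++i) {
    a[i] >>= 1;
    if (i + 1 < a.size() && (a[i + 1] & 1u)) a[i] |= 0x80000000u;
  }
  trim(a);
}

static bool is_even(const Mag &a) { return a.empty() || !(a[0] & 1u); }

// binary gcd
static Mag gcd_mag(Mag a, Mag b) {
  if (a.empty()) return b;
  if (b.empty()) return a;
  size_t shift = 0;
  while (is_even(a) && is_even(b)) { shr1(a); shr1(b); ++shift; }
  while (is_even(a)) shr1(a);
  while (!b.empty()) {
    while (is_even(b)) shr1(b);
    if (cmp_mag(a, b) > 0) std::swap(a, b);
    b = sub_mag(b, a);
  }
  for (size_t i = 0; i < shift; ++i) shl1_or(a, false); // restore common 2s
  return a;
}

struct BigInt {
  int sign; // -1, 0, 1
  Mag mag;
  BigInt() : sign(0) {}
  BigInt(long long v) {
    sign = (v > 0) - (v < 0);
    unsigned long long u = v < 0 ? -(unsigned long long)v : (unsigned long long)v;
    while (u) { mag.push_back((uint32_t)(u & 0xffffffffu)); u >>= 32; }
  }
  bool is_zero() const { return sign == 0; }
};

static BigInt make(int sign, Mag m) {
  BigInt r;
  trim(m);
  r.mag = m;
  r.sign = m.empty() ? 0 : sign;
  return r;
}

static int cmp_bi(const BigInt &a, const BigInt &b) {
  if (a.sign != b.sign) return a.sign < b.sign ? -1 : 1;
  int c = cmp_mag(a.mag, b.mag);
  return a.sign >= 0 ? c : -c;
}

static BigInt add_bi(const BigInt &a, const BigInt &b) {
  if (a.sign == 0) return b;
  if (b.sign == 0) return a;
  if (a.sign == b.sign) return make(a.sign, add_mag(a.mag, b.mag));
  int c = cmp_mag(a.mag, b.mag);
  if (c == 0) return BigInt();
  if (c > 0) return make(a.sign, sub_mag(a.mag, b.mag));
  return make(b.sign, sub_mag(b.mag, a.mag));
}

static BigInt neg_bi(const BigInt &a) { BigInt r = a; r.sign = -r.sign; return r; }
static BigInt sub_bi(const BigInt &a, const BigInt &b) { return add_bi(a, neg_bi(b)); }
static BigInt mul_bi(const BigInt &a, const BigInt &b) {
  if (a.sign == 0 || b.sign == 0) return BigInt();
  return make(a.sign * b.sign, mul_mag(a.mag, b.mag));
}

static std::string mag_to_string(Mag a) {
  if (a.empty()) return "0";
  std::string out;
  while (!a.empty()) {
    uint32_t rem;
    a = div_small(a, 1000000000u, rem);
    char buf[16];
    if (a.empty()) snprintf(buf, sizeof(buf), "%u", rem);
    else snprintf(buf, sizeof(buf), "%09u", rem);
    out = std::string(buf) + out;
  }
  return out;
}

static std::string bi_to_string(const BigInt &a) {
  if (a.sign == 0) return "0";
  std::string s = mag_to_string(a.mag);
  return a.sign < 0 ? "-" + s : s;
}

struct Rat {
  BigInt num;
  Mag den; // > 0; canonical: gcd(|num|, den) == 1
};

static void reduce(Rat &r) {
  if (r.den.empty()) stop("rational with zero denominator");
  if (r.num.sign == 0) { r.den.clear(); r.den.push_back(1); return; }
  Mag g = gcd_mag(r.num.mag, r.den);
  Mag one; one.push_back(1);
  if (cmp_mag(g, one) != 0) {
    Mag q, rem;
    divmod_mag(r.num.mag, g, q, rem);
    r.num.mag = q;
    divmod_mag(r.den, g, q, rem);
    r.den = q;
  }
}

static Mag mag_from_dec(const std::string &s, size_t lo, size_t hi) {
  Mag m;
  for (size_t i = lo; i < hi; ++i) {
    char c = s[i];
    if (c < '0' || c > '9') stop("invalid number '%s'", s.c_str());
    m = mul_small(m, 10);
    m = add_small(m, (uint32_t)(c - '0'));
  }
  return m;
}

// parse "n", "-n", "n/d", "n.m" into canonical Rat
static Rat parse_rat(const std::string &s0) {
  std::string s = s0;
  // strip whitespace
  size_t b = s.find_first_not_of(" \t");
  size_t e = s.find_last_not_of(" \t");
  if (b == std::string::npos) stop("empty rational string");
  s = s.substr(b, e - b + 1);
  Rat r;
  int sign = 1;
  size_t pos = 0;
  if (s[pos] == '-') { sign = -1; ++pos; }
  else if (s[pos] == '+') ++pos;
  size_t slash = s.find('/', pos);
  if (slash != std::string::npos) {
    Mag n = mag_from_dec(s, pos, slash);
    size_t dpos = slash + 1;
    int dsign = 1;
    if (dpos < s.size() && s[dpos] == '-') { dsign = -1; ++dpos; }
    Mag d = mag_from_dec(s, dpos, s.size());
    if (d.empty()) stop("zero denominator in '%s'", s0.c_str());
    r.num = make(sign * dsign, n);
    r.den = d;
  } else {
    size_t dot = s.find('.', pos);
    if (dot != std::string::npos) {
      std::string digits = s.substr(pos, dot - pos) + s.substr(dot + 1);
      size_t frac = s.size() - dot - 1;
      Mag n;
      for (char c : digits) {
        if (c < '0' || c > '9') stop("invalid number '%s'", s0.c_str());
        n = mul_small(n, 10);
        n = add_small(n, (uint32_t)(c - '0'));
      }
      Mag d; d.push_back(1);
      for (size_t i = 0; i < frac; ++i) d = mul_small(d, 10);
      r.num = make(sign, n);
      r.den = d;
    } else {
      Mag n = mag_from_dec(s, pos, s.size());
      r.num = make(sign, n);
      r.den.push_back(1);
    }
  }
  reduce(r);
  return r;
}

static std::string format_rat(const Rat &r) {
  Mag one; one.push_back(1);
  std::string s = bi_to_string(r.num);
  if (r.num.sign != 0 && cmp_mag(r.den, one) != 0)
    s += "/" + mag_to_string(r.den);
  return s;
}

static Rat add_rat(const Rat &a, const Rat &b) {
  Rat r;
  r.num = add_bi(mul_bi(a.num, make(1, b.den)), mul_bi(b.num, make(1, a.den)));
  r.den = mul_mag(a.den, b.den);
  reduce(r);
  return r;
}

static Rat sub_rat(const Rat &a, const Rat &b) {
  Rat r;
  r.num = sub_bi(mul_bi(a.num, make(1, b.den)), mul_bi(b.num, make(1, a.den)));
  r.den = mul_mag(a.den, b.den);
  reduce(r);
  return r;
}

static Rat mul_rat(const Rat &a, const Rat &b) {
  Rat r;
  r.num = mul_bi(a.num, b.num);
  r.den = mul_mag(a.den, b.den);
  reduce(r);
  return r;
}

static Rat div_rat(const Rat &a, const Rat &b) {
  if (b.num.sign == 0) stop("rational division by zero");
  Rat r;
  r.num = mul_bi(a.num, make(b.num.sign, b.den));
  r.den = mul_mag(a.den, b.num.mag);
  reduce(r);
  return r;
}

static int cmp_rat(const Rat &a, const Rat &b) {
  return cmp_bi(mul_bi(a.num, make(1, b.den)), mul_bi(b.num, make(1, a.den)));
}

static double rat_to_dbl(const Rat &r) {
  // exact limbs -> long double; adequate for display/approximation
  long double n = 0, scale = 4294967296.0L;
  for (size_t i = r.num.mag.size(); i-- > 0;) n = n * scale + r.num.mag[i];
  long double d = 0;
  for (size_t i = r.den.size(); i-- > 0;) d = d * scale + r.den[i];
  long double v = d == 0 ? 0 : n / d;
  return (double)(r.num.sign < 0 ? -v : v);
}

// ---- exported (vectorised) interface ----

static R_xlen_t out_len(R_xlen_t na, R_xlen_t nb) {
  if (na == 0 || nb == 0) return 0;
  return std::max(na, nb);
}

// [[Rcpp::export(name = ".rat_canon")]]
CharacterVector rat_canon(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = format_rat(parse_rat(as<std::string>(x[i])));
  }
  return out;
}

// [[Rcpp::export(name = ".rat_arith")]]
CharacterVector rat_arith(std::string op, CharacterVector a, CharacterVector b) {
  R_xlen_t n = out_len(a.size(), b.size());
  CharacterVector out(n);
  int code = op == "+" ? 0 : op == "-" ? 1 : op == "*" ? 2 : op == "/" ? 3 : -1;
  if (code < 0) stop("unknown op '%s'", op.c_str());
  for (R_xlen_t i = 0; i < n; ++i) {
    const String &sa = a[i % a.size()], &sb = b[i % b.size()];
    if (sa == NA_STRING || sb == NA_STRING) { out[i] = NA_STRING; continue; }
    Rat x = parse_rat(sa), y = parse_rat(sb), r;
    switch (code) {
      case 0: r = add_rat(x, y); break;
      case 1: r = sub_rat(x, y); break;
      case 2: r = mul_rat(x, y); break;
      default: r = div_rat(x, y); break;
    }
    out[i] = format_rat(r);
  }
  return out;
}

// [[Rcpp::export(name = ".rat_cmp")]]
IntegerVector rat_cmp_export(CharacterVector a, CharacterVector b) {
  R_xlen_t n = out_len(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const String &sa = a[i % a.size()], &sb = b[i % b.size()];
    if (sa == NA_STRING || sb == NA_STRING) { out[i] = NA_INTEGER; continue; }
    out[i] = cmp_rat(parse_rat(sa), parse_rat(sb));
  }
  return out;
}

// [[Rcpp::export(name = ".rat_sum")]]
CharacterVector rat_sum(CharacterVector x) {
  Rat acc = parse_rat("0");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) stop("NA in rational sum");
    acc = add_rat(acc, parse_rat(as<std::string>(x[i])));
  }
  return CharacterVector::create(format_rat(acc));
}

// [[Rcpp::export(name = ".rat_order")]]
IntegerVector rat_order(CharacterVector x) {
  R_xlen_t n = x.size();
  std::vector<Rat> v(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) stop("NA in rational order");
    v[i] = parse_rat(as<std::string>(x[i]));
  }
  std::vector<int> idx(n);
  for (R_xlen_t i = 0; i < n; ++i) idx[i] = (int)i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int i, int j) { return cmp_rat(v[i], v[j]) < 0; });
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = idx[i] + 1;
  return out;
}

// [[Rcpp::export(name = ".rat_dbl")]]
NumericVector rat_dbl(CharacterVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_REAL; continue; }
    out[i] = rat_to_dbl(parse_rat(as<std::string>(x[i])));
  }
  return out;
}

// round-half-up decimal expansion with `digits` places after the point
// [[Rcpp::export(name = ".rat_decimal")]]
CharacterVector rat_decimal(CharacterVector x, int digits) {
  if (digits < 0) stop("digits must be >= 0");
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    Rat r = parse_rat(as<std::string>(x[i]));
    Mag p; p.push_back(1);
    for (int k = 0; k < digits; ++k) p = mul_small(p, 10);
    // n = round(|num| * 10^digits / den), half away from zero
    Mag scaled = mul_mag(r.num.mag, p);
    Mag twice = mul_small(scaled, 2);
    twice = add_mag(twice, r.den);
    Mag den2 = mul_small(r.den, 2);
    Mag q, rem;
    divmod_mag(twice, den2, q, rem);
    std::string digs = mag_to_string(q);
    std::string res;
    if (digits == 0) res = digs;
    else {
      while (digs.size() < (size_t)digits + 1) digs = "0" + digs;
      res = digs.substr(0, digs.size() - digits) + "." +
            digs.substr(digs.size() - digits);
    }
    if (r.num.sign < 0 && digs.find_first_not_of('0') != std::string::npos)
      res = "-" + res;
    out[i] = res;
  }
  return out;
}
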