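// Byte-level engine primitives.
//
// Records are fixed-width byte sequences; a block of n records is a single
// raw vector of length n * record_size. The first key_size bytes of each
// record are its encoded key; keys are encoded so that memcmp order equals
// semantic (tuple) order, which is what every routine below relies on.
//
// Field kinds: 0 = unsigned-int, 1 = signed-int, 2 = float32, 3 = float64,
// 4 = fixed-ascii. Integers are big-endian; signed integers are biased by
// 2^(8w-1) so that bytewise order equals numeric order.

#include <Rcpp.h>
#include <cstring>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline int keycmp(const unsigned char* a, const unsigned char* b, int ks) {
  int c = std::memcmp(a, b, (size_t)ks);
  return c < 0 ? -1 : (c > 0 ? 1 : 0);
}

// Largest value exactly representable for a w-byte unsigned integer coming
// through an R double (doubles are exact only up to 2^53).
static double uint_max_exact(int w) {
  if (w >= 7) return 9007199254740992.0; // 2^53
  double m = 1.0;
  for (int i = 0; i < w; ++i) m *= 256.0;
  return m - 1.0;
}

static bool is_little_endian() {
  uint16_t x = 1;
  return *reinterpret_cast<unsigned char*>(&x) == 1;
}

// [[Rcpp::export]]
RawVector cxx_encode(List values, IntegerVector widths, IntegerVector kinds,
                     CharacterVector fnames) {
  const int nf = widths.size();
  if (values.size() != nf)
    stop("schema error: expected %d field vectors, got %d", nf, (int)values.size());
  int rs = 0;
  for (int f = 0; f < nf; ++f) rs += widths[f];
  R_xlen_t n = -1;
  for (int f = 0; f < nf; ++f) {
    R_xlen_t len = Rf_xlength(values[f]);
    if (n < 0) n = len;
    else if (len != n)
      stop("schema error: field '%s' has %d values, expected %d",
           CHAR(STRING_ELT(fnames, f)), (int)len, (int)n);
  }
  if (n < 0) n = 0;
  RawVector out((R_xlen_t)n * rs); // zero-initialised
  unsigned char* op = RAW(out);
  const bool le = is_little_endian();

  int off = 0;
  for (int f = 0; f < nf; ++f) {
    const int w = widths[f];
    const int kind = kinds[f];
    const char* fname = CHAR(STRING_ELT(fnames, f));
    if (kind == 4) { // fixed-ascii
      CharacterVector v(values[f]);
      for (R_xlen_t i = 0; i < n; ++i) {
        if (v[i] == NA_STRING)
          stop("range error: field '%s' record %d is NA", fname, (int)i + 1);
        const char* s = CHAR(v[i]);
        size_t len = std::strlen(s);
        if ((int)len > w)
          stop("range error: field '%s' record %d: string of %d bytes exceeds width %d",
               fname, (int)i + 1, (int)len, w);
        std::memcpy(op + i * rs + off, s, len); // remainder stays 0x00 padding
      }
    } else {
      NumericVector v(values[f]);
      if (kind == 0 || kind == 1) { // integers
        const double umax = uint_max_exact(w);
        double bias = 0.0;
        if (kind == 1) { bias = 1.0; for (int j = 0; j < 8 * w - 1; ++j) bias *= 2.0; }
        const double lo = (kind == 1) ? -bias : 0.0;
        const double hi = (kind == 1) ? std::min(bias - 1.0, umax) : umax;
        for (R_xlen_t i = 0; i < n; ++i) {
          double x = v[i];
          if (ISNAN(x))
            stop("range error: field '%s' record %d is NA", fname, (int)i + 1);
          if (x != std::floor(x))
            stop("range error: field '%s' record %d: %.6f is not an integer",
                 fname, (int)i + 1, x);
          if (x < lo || x > hi)
            stop("range error: field '%s' record %d: %.0f outside [%.0f, %.0f]",
                 fname, (int)i + 1, x, lo, hi);
          uint64_t u = (uint64_t)(x + bias);
          unsigned char* p = op + i * rs + off;
          for (int j = w - 1; j >= 0; --j) { p[j] = (unsigned char)(u & 0xFF); u >>= 8; }
        }
      } else if (kind == 2) { // float32 big-endian
        for (R_xlen_t i = 0; i < n; ++i) {
          float fv = (float)v[i];
          unsigned char buf[4];
          std::memcpy(buf, &fv, 4);
          unsigned char* p = op + i * rs + off;
          if (le) for (int j = 0; j < 4; ++j) p[j] = buf[3 - j];
          else    std::memcpy(p, buf, 4);
        }
      } else if (kind == 3) { // float64 big-endian
        for (R_xlen_t i = 0; i < n; ++i) {
          double dv = v[i];
          unsigned char buf[8];
          std::memcpy(buf, &dv, 8);
          unsigned char* p = op + i * rs + off;
          if (le) for (int j = 0; j < 8; ++j) p[j] = buf[7 - j];
          else    std::memcpy(p, buf, 8);
        }
      } else {
        stop("schema error: unknown field kind %d", kind);
      }
    }
    off += w;
  }
  return out;
}

// [[Rcpp::export]]
List cxx_decode(RawVector raw, IntegerVector widths, IntegerVector kinds) {
  const int nf = widths.size();
  int rs = 0;
  for (int f = 0; f < nf; ++f) rs += widths[f];
  if (raw.size() % rs != 0)
    stop("format error: %d bytes is not a multiple of record size %d",
         (int)raw.size(), rs);
  const R_xlen_t n = raw.size() / rs;
  const unsigned char* ip = RAW(raw);
  const bool le = is_little_endian();
  List out(nf);

  int off = 0;
  for (int f = 0; f < nf; ++f) {
    const int w = widths[f];
    const int kind = kinds[f];
    if (kind == 4) {
      CharacterVector v(n);
      for (R_xlen_t i = 0; i < n; ++i) {
        const unsigned char* p = ip + i * rs + off;
        int len = w;
        while (len > 0 && p[len - 1] == 0) --len; // strip NUL padding
        v[i] = std::string((const char*)p, (size_t)len);
      }
      out[f] = v;
    } else if (kind == 0 || kind == 1) {
      double bias = 0.0;
      if (kind == 1) { bias = 1.0; for (int j = 0; j < 8 * w - 1; ++j) bias *= 2.0; }
      NumericVector v(n);
      for (R_xlen_t i = 0; i < n; ++i) {
        const unsigned char* p = ip + i * rs + off;
        double x = 0.0;
        for (int j = 0; j < w; ++j) x = x * 256.0 + (double)p[j];
        v[i] = x - bias;
      }
      out[f] = v;
    } else if (kind == 2) {
      NumericVector v(n);
      for (R_xlen_t i = 0; i < n; ++i) {
        const unsigned char* p = ip + i * rs + off;
        unsigned char buf[4];
        if (le) for (int j = 0; j < 4; ++j) buf[j] = p[3 - j];
        else    std::memcpy(buf, p, 4);
        float fv;
        std::memcpy(&fv, buf, 4);
        v[i] = (double)fv;
      }
      out[f] = v;
    } else if (kind == 3) {
      NumericVector v(n);
      for (R_xlen_t i = 0; i < n; ++i) {
        const unsigned char* p = ip + i * rs + off;
        unsigned char buf[8];
        if (le) for (int j = 0; j < 8; ++j) buf[j] = p[7 - j];
        else    std::memcpy(buf, p, 8);
        double dv;
        std::memcpy(&dv, buf, 8);
        v[i] = dv;
      }
      out[f] = v;
    } else {
      stop("schema error: unknown field kind %d", kind);
    }
    off += w;
  }
  return out;
}

// [[Rcpp::export]]
int cxx_compare_keys(RawVector a, RawVector b) {
  if (a.size() != b.size())
    stop("schema error: key lengths differ (%d vs %d)", (int)a.size(), (int)b.size());
  return keycmp(RAW(a), RAW(b), (int)a.size());
}

// Stable ordering permutation (1-based) of records by key bytes.
// [[Rcpp::export]]
IntegerVector cxx_key_order(RawVector recs, int rs, int ks) {
  const R_xlen_t n = recs.size() / rs;
  const unsigned char* p = RAW(recs);
  std::vector<int> idx((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) idx[(size_t)i] = (int)i;
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    return std::memcmp(p + (size_t)a * rs, p + (size_t)b * rs, (size_t)ks) < 0;
  });
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = idx[(size_t)i] + 1;
  return out;
}

// 0 = strictly sorted unique, 1 = sorted with duplicate keys, 2 = unsorted.
// [[Rcpp::export]]
int cxx_check_sorted(RawVector recs, int rs, int ks) {
  const R_xlen_t n = recs.size() / rs;
  const unsigned char* p = RAW(recs);
  int state = 0;
  for (R_xlen_t i = 1; i < n; ++i) {
    int c = std::memcmp(p + (size_t)(i - 1) * rs, p + (size_t)i * rs, (size_t)ks);
    if (c > 0) return 2;
    if (c == 0) state = 1;
  }
  return state;
}

// Group id (1..g) per record of a key-sorted block; equal keys share an id.
// [[Rcpp::export]]
IntegerVector cxx_dup_groups(RawVector recs, int rs, int ks) {
  const R_xlen_t n = recs.size() / rs;
  const unsigned char* p = RAW(recs);
  IntegerVector gid(n);
  int g = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (i == 0) { g = 1; }
    else {
      int c = std::memcmp(p + (size_t)(i - 1) * rs, p + (size_t)i * rs, (size_t)ks);
      if (c > 0) stop("integrity error: records not sorted by key");
      if (c != 0) ++g;
    }
    gid[i] = g;
  }
  return gid;
}

// [[Rcpp::export]]
RawVector cxx_gather(RawVector recs, int rs, IntegerVector idx) {
  const R_xlen_t n = recs.size() / rs;
  RawVector out((R_xlen_t)idx.size() * rs);
  const unsigned char* ip = RAW(recs);
  unsigned char* op = RAW(out);
  for (R_xlen_t i = 0; i < idx.size(); ++i) {
    int j = idx[i];
    if (j < 1 || j > n) stop("bounds error: record index %d of %d", j, (int)n);
    std::memcpy(op + i * rs, ip + (size_t)(j - 1) * rs, (size_t)rs);
  }
  return out;
}

// [[Rcpp::export]]
RawVector cxx_keys(RawVector recs, int rs, int ks) {
  const R_xlen_t n = recs.size() / rs;
  RawVector out(n * ks);
  const unsigned char* ip = RAW(recs);
  unsigned char* op = RAW(out);
  for (R_xlen_t i = 0; i < n; ++i)
    std::memcpy(op + i * ks, ip + i * rs, (size_t)ks);
  return out;
}

static R_xlen_t lb(const unsigned char* p, R_xlen_t n, int rs, int ks,
                   const unsigned char* key) {
  R_xlen_t lo = 0, hi = n;
  while (lo < hi) {
    R_xlen_t mid = lo + (hi - lo) / 2;
    if (std::memcmp(p + mid * rs, key, (size_t)ks) < 0) lo = mid + 1; else hi = mid;
  }
  return lo;
}

static R_xlen_t ub(const unsigned char* p, R_xlen_t n, int rs, int ks,
                   const unsigned char* key) {
  R_xlen_t lo = 0, hi = n;
  while (lo < hi) {
    R_xlen_t mid = lo + (hi - lo) / 2;
    if (std::memcmp(p + mid * rs, key, (size_t)ks) <= 0) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// First record (1-based) with key >= `key`; n+1 if none.
// [[Rcpp::export]]
int cxx_lower_bound(RawVector recs, int rs, int ks, RawVector key) {
  if ((int)key.size() != ks) stop("schema error: key length %d != key size %d",
                                  (int)key.size(), ks);
  return (int)lb(RAW(recs), recs.size() / rs, rs, ks, RAW(key)) + 1;
}

// First record (1-based) with key > `key`; n+1 if none.
// [[Rcpp::export]]
int cxx_upper_bound(RawVector recs, int rs, int ks, RawVector key) {
  if ((int)key.size() != ks) stop("schema error: key length %d != key size %d",
                                  (int)key.size(), ks);
  return (int)ub(RAW(recs), recs.size() / rs, rs, ks, RAW(key)) + 1;
}

// Bucket id (1-based) per record: 1 + number of boundaries <= key.
// Boundaries are m concatenated encoded keys, strictly ascending.
// [[Rcpp::export]]
IntegerVector cxx_route(RawVector recs, int rs, int ks, RawVector boundaries) {
  const R_xlen_t n = recs.size() / rs;
  const R_xlen_t m = boundaries.size() / ks;
  const unsigned char* p = RAW(recs);
  const unsigned char* bp = RAW(boundaries);
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const unsigned char* key = p + i * rs;
    R_xlen_t lo = 0, hi = m; // count boundaries <= key
    while (lo < hi) {
      R_xlen_t mid = lo + (hi - lo) / 2;
      if (std::memcmp(bp + mid * ks, key, (size_t)ks) <= 0) lo = mid + 1; else hi = mid;
    }
    out[i] = (int)lo + 1;
  }
  return out;
}

// Position (1-based) of each query key in a strictly key-sorted block; NA if absent.
// [[Rcpp::export]]
IntegerVector cxx_match_keys(RawVector recs, int rs, int ks, RawVector qkeys) {
  const R_xlen_t n = recs.size() / rs;
  const R_xlen_t q = qkeys.size() / ks;
  const unsigned char* p = RAW(recs);
  const unsigned char* qp = RAW(qkeys);
  IntegerVector out(q);
  for (R_xlen_t i = 0; i < q; ++i) {
    R_xlen_t pos = lb(p, n, rs, ks, qp + i * ks);
    if (pos < n && std::memcmp(p + pos * rs, qp + i * ks, (size_t)ks) == 0)
      out[i] = (int)pos + 1;
    else
      out[i] = NA_INTEGER;
  }
  return out;
}

// Merge two strictly key-sorted, key-unique blocks. `a` is the existing (disk)
// side, `b` the incoming (memory) side. rule: 1 = replace (b wins),
// 2 = keep_first (a wins), 3 = reduce (a's record is emitted; the collision
// positions are returned so the caller can patch value bytes via its reducer).
// [[Rcpp::export]]
List cxx_merge(RawVector a, RawVector b, int rs, int ks, int rule) {
  const R_xlen_t na = a.size() / rs, nb = b.size() / rs;
  const unsigned char* pa = RAW(a);
  const unsigned char* pb = RAW(b);
  std::vector<unsigned char> out;
  out.reserve((size_t)(na + nb) * rs);
  std::vector<int> apos, bpos, opos;
  R_xlen_t i = 0, j = 0, k = 0;
  while (i < na || j < nb) {
    int c;
    if (i >= na) c = 1;
    else if (j >= nb) c = -1;
    else c = keycmp(pa + i * rs, pb + j * rs, ks);
    if (c < 0) {
      out.insert(out.end(), pa + i * rs, pa + (i + 1) * rs); ++i; ++k;
    } else if (c > 0) {
      out.insert(out.end(), pb + j * rs, pb + (j + 1) * rs); ++j; ++k;
    } else { // collision
      const unsigned char* src = (rule == 1) ? pb + j * rs : pa + i * rs;
      out.insert(out.end(), src, src + rs);
      ++k;
      if (rule == 3) {
        apos.push_back((int)i + 1);
        bpos.push_back((int)j + 1);
        opos.push_back((int)k);
      }
      ++i; ++j;
    }
  }
  RawVector rout(out.size());
  if (!out.empty()) std::memcpy(RAW(rout), out.data(), out.size());
  return List::create(_["records"] = rout,
                      _["a_pos"] = wrap(apos),
                      _["b_pos"] = wrap(bpos),
                      _["out_pos"] = wrap(opos));
}
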