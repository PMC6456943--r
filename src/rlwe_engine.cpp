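// Core ring arithmetic for the RLWE backend: negacyclic NTT over 30-bit
// primes (Shoup-precomputed twiddles, cached per prime), RNS key switching
// with deferred reduction, and CRT reduction of decrypted payloads to the
// plaintext modulus. Residues stay below 2^30, so 64-bit products never
// overflow and up to 16 digit products can accumulate in a uint64.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

typedef uint64_t u64;
typedef unsigned __int128 u128;

static inline u64 mulmod(u64 a, u64 b, u64 q) { return (a * b) % q; }
static inline u64 addmod(u64 a, u64 b, u64 q) { u64 s = a + b; return s >= q ? s - q : s; }
static inline u64 submod(u64 a, u64 b, u64 q) { return a >= b ? a - b : a + q - b; }

static u64 powmod(u64 base, u64 e, u64 q) {
  u64 r = 1 % q; base %= q;
  while (e) { if (e & 1) r = mulmod(r, base, q); base = mulmod(base, base, q); e >>= 1; }
  return r;
}

static inline u64 shoup(u64 w, u64 q) { return (u64)((((u128) w) << 64) / q); }

// x * w mod q with precomputed wsh = floor(w * 2^64 / q); x < q.
static inline u64 shoup_mul(u64 x, u64 w, u64 wsh, u64 q) {
  u64 hi = (u64)(((u128) x * wsh) >> 64);
  u64 r = x * w - hi * q;
  return r >= q ? r - q : r;
}

// Barrett reduction of x < 2^63 with mu = floor(2^64 / q).
struct Barrett {
  u64 q, mu;
  Barrett(u64 q_ = 2) : q(q_), mu((u64)((((u128) 1) << 64) / q_)) {}
  inline u64 red(u64 x) const {
    u64 hi = (u64)(((u128) x * mu) >> 64);
    u64 r = x - hi * q;
    while (r >= q) r -= q;
    return r;
  }
  inline u64 mul(u64 a, u64 b) const { return red(a * b); }
};

static bool is_prime_u64(u64 x) {
  if (x < 2) return false;
  for (u64 d = 2; d * d <= x; ++d) if (x % d == 0) return false;
  return true;
}

struct NTTTab {
  u64 q, psi;
  Barrett bar;
  // tw[len/2 + j] = omega_len^j (omega = psi^2), plus Shoup companions;
  // itw likewise for omega^-1; psi_pows / ipsi_pows fold the negacyclic
  // scaling (ipsi also folds n^-1).
  std::vector<u64> tw, tw_sh, itw, itw_sh, psi_pows, psi_sh, ipsi_pows, ipsi_sh;
};

static std::map<std::pair<u64, u64>, NTTTab> g_tabs;

static const NTTTab &get_tab(u64 q, u64 psi, size_t n) {
  auto key = std::make_pair(q, (u64) n);
  auto it = g_tabs.find(key);
  if (it != g_tabs.end()) return it->second;
  NTTTab t; t.q = q; t.psi = psi; t.bar = Barrett(q);
  u64 omega = mulmod(psi, psi, q);
  u64 omega_inv = powmod(omega, q - 2, q);
  t.tw.assign(n, 1); t.itw.assign(n, 1);
  for (size_t len = 2; len <= n; len <<= 1) {
    u64 w = powmod(omega, n / len, q), wi = powmod(omega_inv, n / len, q);
    u64 cw = 1, cwi = 1;
    for (size_t j = 0; j < len / 2; ++j) {
      t.tw[len / 2 + j] = cw; t.itw[len / 2 + j] = cwi;
      cw = mulmod(cw, w, q); cwi = mulmod(cwi, wi, q);
    }
  }
  u64 psi_inv = powmod(psi, q - 2, q), n_inv = powmod((u64) n, q - 2, q);
  t.psi_pows.assign(n, 1); t.ipsi_pows.assign(n, 1);
  u64 c = 1, ci = n_inv;
  for (size_t j = 0; j < n; ++j) {
    t.psi_pows[j] = c; t.ipsi_pows[j] = ci;
    c = mulmod(c, psi, q); ci = mulmod(ci, psi_inv, q);
  }
  auto mk = [&](const std::vector<u64> &src, std::vector<u64> &dst) {
    dst.resize(src.size());
    for (size_t i = 0; i < src.size(); ++i) dst[i] = shoup(src[i], q);
  };
  mk(t.tw, t.tw_sh); mk(t.itw, t.itw_sh); mk(t.psi_pows, t.psi_sh); mk(t.ipsi_pows, t.ipsi_sh);
  return g_tabs.emplace(key, std::move(t)).first->second;
}

static void bitrev(std::vector<u64> &a) {
  size_t n = a.size();
  for (size_t i = 1, j = 0; i < n; ++i) {
    size_t bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j |= bit;
    if (i < j) std::swap(a[i], a[j]);
  }
}

// Cyclic DFT, natural-order output: X[k] = sum_j a[j] w^(jk).
static void dft(std::vector<u64> &a, const NTTTab &t, bool inverse) {
  size_t n = a.size();
  const std::vector<u64> &tw = inverse ? t.itw : t.tw;
  const std::vector<u64> &tw_sh = inverse ? t.itw_sh : t.tw_sh;
  u64 q = t.q;
  bitrev(a);
  for (size_t len = 2; len <= n; len <<= 1) {
    size_t half = len / 2;
    for (size_t i = 0; i < n; i += len) {
      for (size_t j = 0; j < half; ++j) {
        u64 u = a[i + j];
        u64 v = shoup_mul(a[i + j + half], tw[half + j], tw_sh[half + j], q);
        a[i + j] = addmod(u, v, q);
        a[i + j + half] = submod(u, v, q);
      }
    }
  }
}

// Negacyclic forward: out[k] = poly(psi^(2k+1)); inverse undoes it.
static void ntt_row(std::vector<u64> &a, const NTTTab &t, bool inverse) {
  size_t n = a.size();
  u64 q = t.q;
  if (!inverse) {
    for (size_t j = 0; j < n; ++j)
      a[j] = shoup_mul(a[j] % q, t.psi_pows[j], t.psi_sh[j], q);
    dft(a, t, false);
  } else {
    dft(a, t, true);
    for (size_t j = 0; j < n; ++j)
      a[j] = shoup_mul(a[j], t.ipsi_pows[j], t.ipsi_sh[j], q);
  }
}

// [[Rcpp::export(name = ".eng_powmod")]]
double eng_powmod(double base, double e, double q) {
  return (double) powmod((u64) base, (u64) e, (u64) q);
}

// Primes q = 1 (mod modulo), q < 2^30, descending; `avoid` are excluded.
// [[Rcpp::export(name = ".eng_find_primes")]]
NumericVector eng_find_primes(double modulo, int count, NumericVector avoid) {
  u64 m = (u64) modulo;
  std::vector<double> out;
  u64 k = ((((u64)1) << 30) - 1) / m;
  while ((int) out.size() < count && k > 0) {
    u64 q = m * k + 1;
    bool bad = false;
    for (double a : avoid) if ((u64) a == q) bad = true;
    if (!bad && is_prime_u64(q)) out.push_back((double) q);
    --k;
  }
  if ((int) out.size() < count) stop("not enough NTT primes below 2^30 for this ring");
  return wrap(out);
}

// Primitive (2n)-th root of unity mod prime q (requires 2n | q-1).
// [[Rcpp::export(name = ".eng_primitive_root")]]
double eng_primitive_root(double qd, double nd) {
  u64 q = (u64) qd, n = (u64) nd, m = 2 * n;
  if ((q - 1) % m != 0) stop("2n does not divide q-1");
  std::vector<u64> fac;
  u64 t = q - 1;
  for (u64 d = 2; d * d <= t; ++d) if (t % d == 0) { fac.push_back(d); while (t % d == 0) t /= d; }
  if (t > 1) fac.push_back(t);
  for (u64 g = 2; g < q; ++g) {
    bool ok = true;
    for (u64 f : fac) if (powmod(g, (q - 1) / f, q) == 1) { ok = false; break; }
    if (ok) return (double) powmod(g, (q - 1) / m, q);
  }
  stop("no generator found");
}

// [[Rcpp::export(name = ".eng_ntt")]]
NumericMatrix eng_ntt(NumericMatrix x, NumericVector qs, NumericVector psis, bool inverse) {
  int k = x.nrow(), n = x.ncol();
  NumericMatrix out(k, n);
  std::vector<u64> row(n);
  for (int i = 0; i < k; ++i) {
    const NTTTab &t = get_tab((u64) qs[i], (u64) psis[i], (size_t) n);
    for (int j = 0; j < n; ++j) row[j] = (u64) x(i, j);
    ntt_row(row, t, inverse);
    for (int j = 0; j < n; ++j) out(i, j) = (double) row[j];
  }
  return out;
}

// op: 0 add, 1 sub, 2 mul (componentwise per RNS row)
// [[Rcpp::export(name = ".eng_pw")]]
NumericMatrix eng_pw(NumericMatrix a, NumericMatrix b, NumericVector qs, int op) {
  int k = a.nrow(), n = a.ncol();
  NumericMatrix out(k, n);
  for (int i = 0; i < k; ++i) {
    u64 q = (u64) qs[i];
    Barrett bar(q);
    for (int j = 0; j < n; ++j) {
      u64 x = (u64) a(i, j), y = (u64) b(i, j);
      out(i, j) = (double) (op == 0 ? addmod(x, y, q) : op == 1 ? submod(x, y, q) : bar.mul(x, y));
    }
  }
  return out;
}

// Multiply every RNS row by a per-row scalar.
// [[Rcpp::export(name = ".eng_scale_rows")]]
NumericMatrix eng_scale_rows(NumericMatrix a, NumericVector s, NumericVector qs) {
  int k = a.nrow(), n = a.ncol();
  NumericMatrix out(k, n);
  for (int i = 0; i < k; ++i) {
    u64 q = (u64) qs[i], sc = (u64) s[i] % q;
    Barrett bar(q);
    for (int j = 0; j < n; ++j) out(i, j) = (double) bar.mul((u64) a(i, j), sc);
  }
  return out;
}

// Key switching: `target` (eval domain) sits on a key component that must be
// moved back onto s. Digits are the per-prime residues of its coefficient
// form (CRT idempotent decomposition); ksb/ksa hold one (n_primes x n)
// eval-domain matrix per digit. Returns the (b, a) contribution. Products of
// 30-bit residues are accumulated raw across digits (k <= 16 fits uint64).
// [[Rcpp::export(name = ".eng_keyswitch")]]
List eng_keyswitch(NumericMatrix target, List ksb, List ksa,
                   NumericVector qs, NumericVector psis) {
  int k = target.nrow(), n = target.ncol();
  if (k > 16) stop("more than 16 RNS digits would overflow the accumulator");
  std::vector<std::vector<u64>> coef(k, std::vector<u64>(n));
  for (int i = 0; i < k; ++i) {
    const NTTTab &t = get_tab((u64) qs[i], (u64) psis[i], (size_t) n);
    std::vector<u64> row(n);
    for (int j = 0; j < n; ++j) row[j] = (u64) target(i, j);
    ntt_row(row, t, true);
    coef[i] = row;
  }
  std::vector<std::vector<u64>> bacc(k, std::vector<u64>(n, 0)), aacc(k, std::vector<u64>(n, 0));
  std::vector<u64> drow(n);
  for (int d = 0; d < k; ++d) {
    NumericMatrix kb = ksb[d], ka = ksa[d];
    for (int i = 0; i < k; ++i) {
      u64 q = (u64) qs[i];
      const NTTTab &t = get_tab(q, (u64) psis[i], (size_t) n);
      for (int j = 0; j < n; ++j) drow[j] = coef[d][j] % q;
      ntt_row(drow, t, false);
      for (int j = 0; j < n; ++j) {
        u64 dv = drow[j];
        bacc[i][j] += dv * (u64) kb(i, j);   // deferred reduction
        aacc[i][j] += dv * (u64) ka(i, j);
      }
    }
  }
  NumericMatrix bout(k, n), aout(k, n);
  for (int i = 0; i < k; ++i) {
    u64 q = (u64) qs[i];
    for (int j = 0; j < n; ++j) {
      bout(i, j) = (double) (bacc[i][j] % q);
      aout(i, j) = (double) (aacc[i][j] % q);
    }
  }
  return List::create(_["b"] = bout, _["a"] = aout);
}

// Centered CRT reduction of an RNS coefficient matrix to Z_p, plus the
// observed payload magnitude (largest |centered coefficient| / Q).
// [[Rcpp::export(name = ".eng_crt_mod_p")]]
List eng_crt_mod_p(NumericMatrix x, NumericVector qs, double pd) {
  int k = x.nrow(), n = x.ncol();
  u64 p = (u64) pd;
  std::vector<u64> qhat_inv(k), qhat_mod_p(k);
  u64 Q_mod_p = 1;
  for (int i = 0; i < k; ++i) Q_mod_p = mulmod(Q_mod_p, (u64) qs[i] % p, p);
  for (int i = 0; i < k; ++i) {
    u64 qi = (u64) qs[i], hi = 1, hp = 1;
    for (int j = 0; j < k; ++j) if (j != i) {
      hi = mulmod(hi, (u64) qs[j] % qi, qi);
      hp = mulmod(hp, (u64) qs[j] % p, p);
    }
    qhat_inv[i] = powmod(hi, qi - 2, qi);
    qhat_mod_p[i] = hp;
  }
  NumericVector vals(n);
  double max_frac = 0.0;
  for (int j = 0; j < n; ++j) {
    long double f = 0.0L;
    u64 acc = 0;
    for (int i = 0; i < k; ++i) {
      u64 qi = (u64) qs[i];
      u64 yi = mulmod((u64) x(i, j), qhat_inv[i], qi);
      f += (long double) yi / (long double) qi;
      acc = addmod(acc, mulmod(yi, qhat_mod_p[i], p), p);
    }
    long long r = (long long) llroundl(f);
    long double frac = fabsl(f - (long double) r);
    if (frac > max_frac) max_frac = (double) frac;
    u64 rp = (u64) (((long long) (r % (long long) p) + (long long) p) % (long long) p);
    vals[j] = (double) submod(acc, mulmod(rp, Q_mod_p, p), p);
  }
  return List::create(_["values"] = vals, _["max_frac"] = max_frac);
}

static inline int ham(const char *a, const char *b, int len, int stop_at) {
  int d = 0;
  for (int i = 0; i < len; ++i) { if (a[i] != b[i]) { if (++d > stop_at) return d; } }
  return d;
}

// Pairs at Hamming distance <= pdt. within=TRUE checks i<j pairs of `a`
// (b ignored); otherwise all a-by-b pairs. Pairs with equal locus keys are
// exempt. Reports up to max_viol offending pairs (1-based indices).
// [[Rcpp::export(name = ".eng_close_pairs")]]
List eng_close_pairs(CharacterVector a, CharacterVector b,
                     IntegerVector key_a, IntegerVector key_b,
                     int pdt, bool within, int max_viol) {
  int na = a.size();
  std::vector<const char *> ap(na);
  std::vector<int> alen(na);
  for (int i = 0; i < na; ++i) { ap[i] = CHAR(STRING_ELT(a, i)); alen[i] = LENGTH(STRING_ELT(a, i)); }
  std::vector<int> vi, vj, vd;
  bool full = false;
  if (within) {
    for (int i = 0; i < na && !full; ++i)
      for (int j = i + 1; j < na; ++j) {
        if (key_a[i] == key_a[j]) continue;
        if (alen[i] != alen[j]) stop("k-mer length mismatch");
        int d = ham(ap[i], ap[j], alen[i], pdt);
        if (d <= pdt) {
          vi.push_back(i + 1); vj.push_back(j + 1); vd.push_back(d);
          if ((int) vi.size() >= max_viol) { full = true; break; }
        }
      }
  } else {
    int nb = b.size();
    std::vector<const char *> bp(nb);
    for (int j = 0; j < nb; ++j) bp[j] = CHAR(STRING_ELT(b, j));
    for (int i = 0; i < na && !full; ++i)
      for (int j = 0; j < nb; ++j) {
        if (key_a[i] == key_b[j]) continue;
        if (alen[i] != LENGTH(STRING_ELT(b, j))) stop("k-mer length mismatch");
        int d = ham(ap[i], bp[j], alen[i], pdt);
        if (d <= pdt) {
          vi.push_back(i + 1); vj.push_back(j + 1); vd.push_back(d);
          if ((int) vi.size() >= max_viol) { full = true; break; }
        }
      }
  }
  return List::create(_["ok"] = vi.empty(), _["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["dist"] = wrap(vd));
}
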