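// Table-driven GF(2^m) arithmetic and systematic Reed-Solomon coding with
// errors-and-erasures decoding. One engine serves both the short inner code
// (m = 6, n = 20, k = 18) and the long outer code (m = 14, n = 16383,
// k = 10977); shortened codes (n < 2^m - 1) are supported by the same
// generator-polynomial encoder and Berlekamp-Massey decoder.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include "rng.h"

using namespace Rcpp;

namespace {

struct GF {
  int m, q;                 // q = 2^m
  std::vector<int> exp_;    // exp_[i] = alpha^i, doubled so log sums index directly
  std::vector<int> log_;    // log_[a] for a != 0; log_[0] = -1 (unused)
  GF(int m_, int poly) : m(m_), q(1 << m_), exp_(2 * (1 << m_)), log_(1 << m_, -1) {
    int x = 1;
    for (int i = 0; i < q - 1; ++i) {
      exp_[i] = x;
      log_[x] = i;
      x <<= 1;
      if (x & q) x ^= poly;
    }
    for (int i = q - 1; i < 2 * q; ++i) exp_[i] = exp_[i - (q - 1)];
  }
  inline int mul(int a, int b) const {
    if (a == 0 || b == 0) return 0;
    return exp_[log_[a] + log_[b]];
  }
  inline int inv(int a) const { return exp_[q - 1 - log_[a]]; }
  inline int div(int a, int b) const {
    if (a == 0) return 0;
    return exp_[log_[a] - log_[b] + q - 1];
  }
  // alpha^e for any integer e (possibly negative)
  inline int pow_alpha(long long e) const {
    long long r = e % (q - 1);
    if (r < 0) r += q - 1;
    return exp_[r];
  }
};

// generator polynomial g(x) = prod_{j=0}^{nk-1} (x - alpha^{fcr+j}),
// coefficients lowest-degree first, g[nk] = 1 (monic)
std::vector<int> genpoly(const GF& gf, int nk, int fcr) {
  std::vector<int> g(nk + 1, 0);
  g[0] = 1;
  int deg = 0;
  for (int j = 0; j < nk; ++j) {
    int root = gf.pow_alpha(fcr + j);
    for (int i = deg + 1; i >= 1; --i) g[i] = g[i - 1] ^ gf.mul(root, g[i]);
    g[0] = gf.mul(root, g[0]);
    ++deg;
  }
  return g;
}

// Systematic encode of one message (msg[0] transmitted first). Codeword
// layout: c[0..k-1] = message, c[k..n-1] = parity. Polynomial convention:
// vector position i holds the coefficient of x^(n-1-i).
void rs_encode_one(const GF& gf, const std::vector<int>& g, int n, int k,
                   const int* msg, int* out) {
  int nk = n - k;
  std::vector<int> par(nk, 0); // par[j] = coefficient of x^j of running remainder
  for (int i = 0; i < k; ++i) {
    int f = msg[i] ^ par[nk - 1];
    for (int j = nk - 1; j >= 1; --j)
      par[j] = par[j - 1] ^ gf.mul(f, g[j]);
    par[0] = gf.mul(f, g[0]);
    out[i] = msg[i];
  }
  for (int j = 0; j < nk; ++j) out[k + j] = par[nk - 1 - j];
}

// syndromes S_j = c(alpha^{fcr+j}), j = 0..nk-1, via Horner in transmit order
void syndromes(const GF& gf, const int* cw, int n, int nk, int fcr,
               std::vector<int>& S) {
  for (int j = 0; j < nk; ++j) {
    int x = gf.pow_alpha(fcr + j);
    int acc = 0;
    for (int i = 0; i < n; ++i) acc = gf.mul(acc, x) ^ cw[i];
    S[j] = acc;
  }
}

// poly multiply (lowest-first), truncated to maxlen coefficients
std::vector<int> poly_mul_trunc(const GF& gf, const std::vector<int>& a,
                                const std::vector<int>& b, size_t maxlen) {
  std::vector<int> c(std::min(maxlen, a.size() + b.size() - 1), 0);
  for (size_t i = 0; i < a.size(); ++i) {
    if (!a[i]) continue;
    for (size_t j = 0; j < b.size() && i + j < c.size(); ++j)
      if (b[j]) c[i + j] ^= gf.mul(a[i], b[j]);
  }
  return c;
}

inline int poly_eval(const GF& gf, const std::vector<int>& p, int x) {
  int acc = 0;
  for (size_t i = p.size(); i-- > 0;) acc = gf.mul(acc, x) ^ p[i];
  return acc;
}

struct DecodeOut {
  bool ok;
  int nerr;   // corrected errors outside erasures
  int neras;  // erasure positions filled
};

// Errors-and-erasures decoder: Berlekamp-Massey initialized with the erasure
// locator, Chien search over the n code positions, Forney error values,
// followed by a full syndrome re-check (hard failure instead of silent
// corruption). received[i] == -1 marks an erasure. On success `received` is
// replaced by the corrected codeword.
DecodeOut rs_decode_one(const GF& gf, int n, int k, int fcr,
                        std::vector<int>& received) {
  int nk = n - k;
  DecodeOut out{false, 0, 0};
  std::vector<int> eras_pos; // polynomial positions p = n-1-i
  for (int i = 0; i < n; ++i) {
    if (received[i] < 0) {
      eras_pos.push_back(n - 1 - i);
      received[i] = 0;
    }
  }
  int rho = (int)eras_pos.size();
  if (rho > nk) return out;

  std::vector<int> S(nk);
  syndromes(gf, received.data(), n, nk, fcr, S);
  bool all_zero = true;
  for (int j = 0; j < nk; ++j)
    if (S[j]) { all_zero = false; break; }
  if (all_zero && rho == 0) {
    out.ok = true;
    return out;
  }

  // erasure locator Gamma(x) = prod (1 - alpha^p x)
  std::vector<int> gamma(1, 1);
  for (int p : eras_pos) {
    std::vector<int> term{1, gf.pow_alpha(p)};
    gamma = poly_mul_trunc(gf, gamma, term, gamma.size() + 1);
  }

  // Berlekamp-Massey with erasure initialization: Lambda = B = Gamma
  std::vector<int> lam = gamma, B = gamma;
  int L = rho;
  for (int r = rho; r < nk; ++r) {
    int delta = 0;
    for (size_t i = 0; i < lam.size() && (int)i <= r; ++i)
      if (lam[i]) delta ^= gf.mul(lam[i], S[r - i]);
    B.insert(B.begin(), 0); // B <- x * B
    if (delta != 0) {
      std::vector<int> T(std::max(lam.size(), B.size()), 0);
      for (size_t i = 0; i < lam.size(); ++i) T[i] = lam[i];
      for (size_t i = 0; i < B.size(); ++i) T[i] ^= gf.mul(delta, B[i]);
      if (2 * L <= r + rho) {
        int dinv = gf.inv(delta);
        B.assign(lam.size(), 0);
        for (size_t i = 0; i < lam.size(); ++i) B[i] = gf.mul(dinv, lam[i]);
        L = r + 1 - L + rho;
      }
      lam = T;
    }
  }
  while (lam.size() > 1 && lam.back() == 0) lam.pop_back();
  int deg = (int)lam.size() - 1;
  if (deg > nk) return out;

  // Omega(x) = S(x) * Lambda(x) mod x^nk
  std::vector<int> omega = poly_mul_trunc(gf, S, lam, nk);

  // Chien search over polynomial positions 0..n-1
  std::vector<int> err_pos;
  for (int p = 0; p < n; ++p) {
    int xinv = gf.pow_alpha(-(long long)p);
    if (poly_eval(gf, lam, xinv) == 0) err_pos.push_back(p);
  }
  if ((int)err_pos.size() != deg) return out; // locator inconsistent

  // Forney: e_p = X^{1-fcr} * Omega(X^{-1}) / Lambda'(X^{-1});
  // formal derivative in characteristic 2 keeps only odd-degree terms
  std::vector<int> lam_deriv(lam.size() > 1 ? lam.size() - 1 : 1, 0);
  for (size_t i = 1; i < lam.size(); i += 2) lam_deriv[i - 1] = lam[i];

  int n_erase_filled = 0, n_err = 0;
  std::vector<bool> is_erasure(n, false);
  for (int p : eras_pos) is_erasure[p] = true;
  for (int p : err_pos) {
    int xinv = gf.pow_alpha(-(long long)p);
    int denom = poly_eval(gf, lam_deriv, xinv);
    if (denom == 0) return out;
    int num = poly_eval(gf, omega, xinv);
    int mag = gf.div(num, denom);
    mag = gf.mul(mag, gf.pow_alpha((long long)(1 - fcr) * p));
    int i = n - 1 - p;
    received[i] ^= mag;
    if (is_erasure[p]) {
      ++n_erase_filled;
    } else if (mag != 0) {
      ++n_err;
    }
  }

  std::vector<int> S2(nk);
  syndromes(gf, received.data(), n, nk, fcr, S2);
  for (int j = 0; j < nk; ++j)
    if (S2[j]) return out;

  out.ok = true;
  out.nerr = n_err;
  out.neras = rho;
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_gf_tables(int m, int poly) {
  GF gf(m, poly);
  IntegerVector ex(gf.q - 1), lg(gf.q);
  for (int i = 0; i < gf.q - 1; ++i) ex[i] = gf.exp_[i];
  lg[0] = NA_INTEGER;
  for (int a = 1; a < gf.q; ++a) lg[a] = gf.log_[a];
  return List::create(_["exp"] = ex, _["log"] = lg);
}

// [[Rcpp::export]]
IntegerVector cpp_gf_mul(IntegerVector a, IntegerVector b, int m, int poly) {
  GF gf(m, poly);
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = gf.mul(a[i % a.size()], b[i % b.size()]);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_rs_genpoly(int m, int poly, int n, int k, int fcr) {
  GF gf(m, poly);
  std::vector<int> g = genpoly(gf, n - k, fcr);
  return IntegerVector(g.begin(), g.end());
}

// Encode many messages at once: `messages` is (n_messages x k); returns
// (n_messages x n) systematic codewords.
// [[Rcpp::export]]
IntegerMatrix cpp_rs_encode_many(IntegerMatrix messages, int m, int poly,
                                 int n, int k, int fcr) {
  GF gf(m, poly);
  std::vector<int> g = genpoly(gf, n - k, fcr);
  int nm = messages.nrow();
  IntegerMatrix out(nm, n);
  std::vector<int> msg(k), cw(n);
  for (int r = 0; r < nm; ++r) {
    for (int i = 0; i < k; ++i) msg[i] = messages(r, i);
    rs_encode_one(gf, g, n, k, msg.data(), cw.data());
    for (int i = 0; i < n; ++i) out(r, i) = cw[i];
  }
  return out;
}

// Decode many received words; NA or -1 entries mark erasures. Returns the
// corrected codewords (row unchanged on failure) plus per-row status.
// [[Rcpp::export]]
List cpp_rs_decode_many(IntegerMatrix received, int m, int poly,
                        int n, int k, int fcr) {
  GF gf(m, poly);
  int nm = received.nrow();
  IntegerMatrix cw(nm, n);
  LogicalVector ok(nm);
  IntegerVector nerr(nm), neras(nm);
  std::vector<int> r(n);
  for (int row = 0; row < nm; ++row) {
    for (int i = 0; i < n; ++i) {
      int v = received(row, i);
      r[i] = (v == NA_INTEGER || v < 0) ? -1 : v;
    }
    DecodeOut d = rs_decode_one(gf, n, k, fcr, r);
    ok[row] = d.ok;
    nerr[row] = d.nerr;
    neras[row] = d.neras;
    for (int i = 0; i < n; ++i) cw(row, i) = r[i];
  }
  return List::create(_["codeword"] = cw, _["ok"] = ok,
                      _["n_errors"] = nerr, _["n_erasures"] = neras);
}

// Pseudo-random keystream bits for payload scrambling: one independent
// stream per (seed, stream id) pair, bits emitted MSB-first from successive
// 64-bit words.
// [[Rcpp::export]]
IntegerMatrix cpp_keystream_matrix(double seed, IntegerVector streams, int nbits) {
  int nr = streams.size();
  IntegerMatrix out(nr, nbits);
  for (int r = 0; r < nr; ++r) {
    uint64_t init = mix64((uint64_t)seed * 0x9E3779B97F4A7C15ULL ^
                          mix64((uint64_t)(uint32_t)streams[r] + 0x5851F42D4C957F2DULL));
    SplitMix64 rng(init);
    int b = 0;
    while (b < nbits) {
      uint64_t w = rng.next();
      for (int j = 63; j >= 0 && b < nbits; --j, ++b)
        out(r, b) = (int)((w >> j) & 1ULL);
    }
  }
  return out;
}
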