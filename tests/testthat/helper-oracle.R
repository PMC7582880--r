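# Independent schoolbook reference implementations used as oracles.
# Deliberately written in plain R with no calls into the package's compiled
# arithmetic: field multiplication by shift-and-xor with polynomial
# reduction, generator polynomials by convolution, encoding by polynomial
# long division.

oracle_gf_mul <- function(a, b, m, poly) {
  r <- 0L
  while (b > 0L) {
    if (bitwAnd(b, 1L) == 1L) r <- bitwXor(r, a)
    b <- bitwShiftR(b, 1L)
    a <- bitwShiftL(a, 1L)
    if (bitwAnd(a, bitwShiftL(1L, m)) != 0L) a <- bitwXor(a, poly)
  }
  r
}

oracle_gf_pow <- function(a, e, m, poly) {
  r <- 1L
  for (i in seq_len(e)) r <- oracle_gf_mul(r, a, m, poly)
  r
}

# generator polynomial prod_{j=fcr}^{fcr+nk-1} (x - alpha^j),
# lowest-degree-first coefficients
oracle_genpoly <- function(nk, m, poly, fcr = 1L) {
  g <- 1L
  for (j in seq_len(nk) - 1L) {
    root <- oracle_gf_pow(2L, fcr + j, m, poly)
    ng <- integer(length(g) + 1L)
    ng[2:(length(g) + 1L)] <- g                      # x * g
    for (i in seq_along(g)) {
      ng[i] <- bitwXor(ng[i], oracle_gf_mul(root, g[i], m, poly))
    }
    g <- ng
  }
  g
}

# systematic RS encoding by long division of x^(n-k) * m(x) by g(x);
# message symbols first, then parity (same layout as the package)
oracle_rs_encode <- function(msg, n, k, m, poly, fcr = 1L) {
  nk <- n - k
  g <- oracle_genpoly(nk, m, poly, fcr)       # degree nk, g[nk+1] = 1
  # dividend coefficients, highest degree first: msg then nk zeros
  rem <- integer(nk)                          # highest degree first
  for (s in msg) {
    f <- bitwXor(s, rem[1])
    rem <- c(rem[-1], 0L)
    if (f != 0L) {
      # subtract f * g; g highest-first is rev(g)[-1] after the monic term
      gh <- rev(g)[-1]
      for (i in seq_len(nk)) {
        rem[i] <- bitwXor(rem[i], oracle_gf_mul(f, gh[i], m, poly))
      }
    }
  }
  c(msg, rem)
}

oracle_syndromes <- function(cw, nk, m, poly, fcr = 1L) {
  vapply(seq_len(nk) - 1L, function(j) {
    x <- oracle_gf_pow(2L, fcr + j, m, poly)
    acc <- 0L
    for (s in cw) acc <- bitwXor(oracle_gf_mul(acc, x, m, poly), s)
    acc
  }, integer(1))
}

# brute-force global alignment score by recursive enumeration (tiny strings)
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  n <- nchar(a)
  m <- nchar(b)
  if (n == 0) return(m * gap)
  if (m == 0) return(n * gap)
  ca <- substr(a, n, n)
  cb <- substr(b, m, m)
  max(
    oracle_align_score(substr(a, 1, n - 1), substr(b, 1, m - 1)) +
      (if (ca == cb) match else mismatch),
    oracle_align_score(substr(a, 1, n - 1), b) + gap,
    oracle_align_score(a, substr(b, 1, m - 1)) + gap
  )
}

random_dna <- function(n, len = 60) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

random_bytes <- function(n) as.raw(sample(0:255, n, replace = TRUE))

# small code layout used throughout the unit tests (fast full encodes)
test_params <- function(blocks = 1L) {
  code_params(N = 255L, K = 171L, blocks = blocks)
}
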