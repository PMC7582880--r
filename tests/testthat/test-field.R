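# GF(2^m) arithmetic and the Reed-Solomon errors-and-erasures engine,
# checked against plain-R schoolbook oracles and by exhaustive enumeration
# on small codes.

test_that("exp/log tables round-trip and the generator spans the field", {
  for (m in c(3, 6, 8, 14)) {
    f <- gf_field(m)
    expect_equal(sort(f$exp), seq_len(f$order - 1L))
    nz <- seq_len(f$order - 1L)
    expect_equal(f$exp[f$log[nz + 1L] + 1L], nz)
  }
})

test_that("alpha has full multiplicative order in GF(2^6) (brute force)", {
  f <- gf_field(6)
  x <- 1L
  orders <- integer(0)
  for (i in 1:63) {
    x <- gf_mul(x, 2L, f)
    if (x == 1L) orders <- c(orders, i)
  }
  expect_equal(orders, 63L)
})

test_that("field arithmetic satisfies the ring axioms on random triples", {
  withr::local_seed(101)
  for (m in c(3, 6, 8, 14)) {
    f <- gf_field(m)
    a <- sample(0:(f$order - 1L), 50, replace = TRUE)
    b <- sample(0:(f$order - 1L), 50, replace = TRUE)
    c <- sample(0:(f$order - 1L), 50, replace = TRUE)
    expect_equal(gf_mul(a, b, f), gf_mul(b, a, f))
    expect_equal(gf_mul(gf_mul(a, b, f), c, f), gf_mul(a, gf_mul(b, c, f), f))
    expect_equal(gf_mul(a, gf_add(b, c, f), f),
                 gf_add(gf_mul(a, b, f), gf_mul(a, c, f), f))
    expect_equal(gf_mul(a, 0L, f), rep(0L, 50))
    expect_equal(gf_mul(a, 1L, f), a)
    nz <- a[a != 0L]
    expect_equal(gf_mul(nz, gf_inv(nz, f), f), rep(1L, length(nz)))
  }
})

test_that("gf_mul agrees with the shift-and-xor oracle", {
  withr::local_seed(102)
  for (m in c(3, 6, 14)) {
    f <- gf_field(m)
    for (i in 1:40) {
      a <- sample(0:(f$order - 1L), 1)
      b <- sample(0:(f$order - 1L), 1)
      expect_identical(gf_mul(a, b, f),
                       oracle_gf_mul(a, b, m, f$primitive_poly))
    }
  }
})

test_that("non-primitive polynomials are rejected", {
  expect_error(gf_field(4, 0x1F), "not primitive") # x^4+x^3+x^2+x+1, order 5
  expect_error(gf_field(6, 0x1B), "degree")
})

test_that("systematic encoding matches the long-division oracle", {
  withr::local_seed(103)
  f3 <- gf_field(3)
  rs <- rs_params(f3, 7, 3)
  expect_equal(rs_encode(c(0L, 0L, 0L), rs), rep(0L, 7))
  for (i in 1:20) {
    msg <- sample(0:7, 3, replace = TRUE)
    expect_equal(rs_encode(msg, rs),
                 oracle_rs_encode(msg, 7, 3, 3, f3$primitive_poly))
  }
  # larger standard code over GF(2^8)
  f8 <- gf_field(8)
  rs255 <- rs_params(f8, 255, 223)
  for (i in 1:100) {
    msg <- sample(0:255, 223, replace = TRUE)
    cw <- rs_encode(msg, rs255)
    expect_equal(cw, oracle_rs_encode(msg, 255, 223, 8, f8$primitive_poly))
  }
})

test_that("codewords have all-zero syndromes", {
  withr::local_seed(104)
  f6 <- gf_field(6)
  rs <- rs_params(f6, 20, 18)
  for (i in 1:10) {
    cw <- rs_encode(sample(0:63, 18, replace = TRUE), rs)
    expect_equal(oracle_syndromes(cw, 2, 6, f6$primitive_poly), c(0L, 0L))
  }
})

test_that("RS(7,3) corrects every pattern of up to 2 symbol errors", {
  f3 <- gf_field(3)
  rs <- rs_params(f3, 7, 3)
  msg <- c(1L, 5L, 3L)
  cw <- rs_encode(msg, rs)

  d <- rs_decode(cw, rs)
  expect_true(d$ok)
  expect_equal(d$n_errors, 0L)
  expect_equal(d$message, msg)

  for (p1 in 1:7) {
    for (v1 in 1:7) {
      r <- cw
      r[p1] <- bitwXor(r[p1], v1)
      d <- rs_decode(r, rs)
      expect_true(d$ok)
      expect_equal(d$message, msg)
    }
  }
  for (p1 in 1:6) {
    for (p2 in (p1 + 1):7) {
      for (v1 in 1:7) {
        for (v2 in 1:7) {
          r <- cw
          r[p1] <- bitwXor(r[p1], v1)
          r[p2] <- bitwXor(r[p2], v2)
          d <- rs_decode(r, rs)
          expect_true(d$ok)
          expect_equal(d$message, msg)
        }
      }
    }
  }
})

test_that("RS(7,3) fills up to 4 erasures, alone or mixed with errors", {
  f3 <- gf_field(3)
  rs <- rs_params(f3, 7, 3)
  msg <- c(6L, 0L, 2L)
  cw <- rs_encode(msg, rs)

  d <- rs_decode(cw, rs, erasures = c(1, 3, 5, 7))
  expect_true(d$ok)
  expect_equal(d$message, msg)
  expect_equal(d$n_erasures, 4L)

  r <- cw
  r[2] <- bitwXor(r[2], 3L)
  d <- rs_decode(r, rs, erasures = c(5, 6))
  expect_true(d$ok)
  expect_equal(d$message, msg)
  expect_equal(d$n_errors, 1L)

  expect_false(rs_decode(cw, rs, erasures = 1:5)$ok)
})

test_that("RS(20,18) corrects any single symbol error and fills 2 erasures", {
  withr::local_seed(105)
  f6 <- gf_field(6)
  rs <- rs_params(f6, 20, 18)
  msg <- sample(0:63, 18, replace = TRUE)
  cw <- rs_encode(msg, rs)

  for (p in 1:20) {
    for (v in 1:63) {
      r <- cw
      r[p] <- bitwXor(r[p], v)
      d <- rs_decode(r, rs)
      expect_true(d$ok)
      expect_equal(d$message, msg)
    }
  }
  for (i in 1:20) {
    er <- sample(1:20, 2)
    d <- rs_decode(cw, rs, erasures = er)
    expect_true(d$ok)
    expect_equal(d$message, msg)
  }
  # 1 error + 1 erasure exceeds the radius (2e + eps = 3 > 2): the decoder
  # may fail outright or miscorrect onto a *different* codeword (minimum
  # distance 3), but a success must always be a consistent codeword -
  # never an arbitrary non-codeword
  for (i in 1:50) {
    r <- cw
    p <- sample(1:20, 2)
    r[p[1]] <- bitwXor(r[p[1]], sample(1:63, 1))
    d <- rs_decode(r, rs, erasures = p[2])
    if (d$ok) {
      expect_equal(rs_encode(d$message, rs), d$codeword)
    }
  }
})

test_that("random error/erasure mixes within the radius always decode", {
  withr::local_seed(106)
  f6 <- gf_field(6)
  rs <- rs_params(f6, 63, 45)
  nk <- 18L
  for (trial in 1:1000) {
    msg <- sample(0:63, 45, replace = TRUE)
    cw <- rs_encode(msg, rs)
    eps <- sample(0:nk, 1)
    e <- if (nk - eps >= 2) sample(0:((nk - eps) %/% 2), 1) else 0L
    pos <- sample(1:63, e + eps)
    r <- cw
    if (e > 0) {
      for (p in pos[seq_len(e)]) r[p] <- bitwXor(r[p], sample(1:63, 1))
    }
    er <- if (eps > 0) pos[e + seq_len(eps)] else integer(0)
    d <- rs_decode(r, rs, erasures = er)
    expect_true(d$ok)
    expect_equal(d$message, msg)
  }
})

test_that("matrix encode/decode round-trips for both production codes", {
  withr::local_seed(107)
  # inner-code shape
  f6 <- gf_field(6)
  rs <- rs_params(f6, 20, 18)
  msgs <- matrix(sample(0:63, 18 * 25, replace = TRUE), nrow = 25)
  cws <- rs_encode(msgs, rs)
  expect_equal(dim(cws), c(25L, 20L))
  expect_equal(cws[, 1:18], msgs)
  # shortened outer-code shape over GF(2^14)
  f14 <- gf_field(14)
  rs_s <- rs_params(f14, 300, 201)
  msg <- sample(0:(2^14 - 1), 201, replace = TRUE)
  cw <- rs_encode(msg, rs_s)
  r <- cw
  hit <- sample(1:300, 40)
  r[hit[1:20]] <- NA # erasures
  for (p in hit[21:35]) r[p] <- bitwXor(r[p], sample(1:(2^14 - 1), 1))
  d <- rs_decode(r, rs_s) # 2*15 + 20 = 50 <= 99
  expect_true(d$ok)
  expect_equal(d$message, msg)
  expect_equal(d$n_erasures, 20L)
})
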