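# File <-> oligo codec: framing, randomization, outer/inner encoding,
# sequence layout, and the inverse path.

test_that("scrambling is an involution and decorrelates rows", {
  withr::local_seed(201)
  b <- sample(0:1, 840, replace = TRUE)
  expect_identical(scramble_bits(scramble_bits(b, 11L), 11L), as.integer(b))
  expect_false(identical(scramble_bits(b, 11L), as.integer(b)))
  # distinct rows scrambled with distinct streams are near-orthogonal:
  # normalized Hamming distance concentrates at 1/2
  zero <- integer(84)
  rows <- vapply(0:299, function(s) scramble_bits(zero, 5L, stream = s),
                 integer(84))
  d <- vapply(1:299, function(i) mean(rows[, i] != rows[, i + 1]), numeric(1))
  expect_gt(mean(d), 0.45)
  expect_lt(mean(d), 0.55)
})

test_that("keystream output avoids long homopolymers after base mapping", {
  hp <- vapply(1:200, function(s) {
    bits <- scramble_bits(integer(2400), s)
    max_homopolymer(bits_to_dna(matrix(bits, nrow = 1)))
  }, integer(1))
  expect_gte(mean(hp <= 12), 0.99)
})

test_that("payload framing round-trips and enforces capacity", {
  p <- test_params()
  expect_equal(unframe_payload(frame_payload(raw(0), p)), raw(0))
  withr::local_seed(202)
  for (n in c(1, 100, 1500)) {
    b <- random_bytes(n)
    fr <- frame_payload(b, p)
    expect_equal(nrow(fr$rows), p$K)
    expect_identical(unframe_payload(fr), b)
  }
  too_big <- raw(payload_capacity_bytes(p) + 1)
  expect_error(frame_payload(too_big, p), "capacity")
})

test_that("outer encoding is systematic and adds N - K redundancy rows", {
  p <- test_params()
  fr <- frame_payload(raw(0), p)
  enc <- outer_encode(fr, p)
  expect_equal(nrow(enc), p$N)
  expect_true(all(enc == 0L))

  withr::local_seed(203)
  fr <- frame_payload(random_bytes(1000), p)
  enc <- outer_encode(fr, p)
  expect_equal(enc[seq_len(p$K), ], fr$rows) # systematic
  expect_equal(nrow(enc) - p$K, outer_redundancy(p))
})

test_that("full-scale layout arithmetic matches the design", {
  p <- code_params()
  expect_equal(outer_redundancy(p), 5406)
  expect_equal(raw_capacity_bytes(p), 245745)
  expect_equal(round(net_density(p), 3), 0.938)
  expect_equal(round(100 * erasure_bound(p)), 33)
  expect_equal(p$inner_n * p$symbol_bits, 120)
  expect_equal(p$index_bits + p$payload_bits, p$inner_k * p$symbol_bits)
  # the stored 99,103-byte file fits the default parameters
  expect_gte(p$K * p$payload_bits, 64 + 8 * 99103)
})

test_that("assembled sequences carry the index at nt 40-51 behind ACAAC", {
  p <- test_params()
  withr::local_seed(204)
  rows <- matrix(sample(0:1, 84 * 50, replace = TRUE), nrow = 50)
  idx <- sample(0:(p$N - 1), 50)
  seqs <- assemble_sequence(rows, idx, p)
  expect_true(all(nchar(seqs) == 60))
  expect_true(all(grepl("^[ACGT]+$", seqs)))
  expect_true(all(substr(seqs, 40, 44) == "ACAAC"))
  # round-trip through the inner decoder recovers row and index
  dec <- inner_decode(seqs, p)
  expect_true(all(dec$ok))
  expect_equal(dec$index, as.integer(idx))
  expect_equal(dec$row, apply(rows, 1, paste, collapse = ""))
  expect_error(assemble_sequence(rows[1, ], 2^24, p), "index")
})

test_that("any index below 2^14 keeps the constant 5-nt index prefix", {
  p <- code_params() # full N so indices up to 16382 are legal
  withr::local_seed(205)
  row <- sample(0:1, 84, replace = TRUE)
  for (i in c(0L, 1L, 255L, 5000L, 16382L)) {
    expect_equal(substr(assemble_sequence(row, i, p), 40, 44), "ACAAC")
  }
})

test_that("inner decoding survives any single-nucleotide substitution", {
  p <- test_params()
  withr::local_seed(206)
  s <- assemble_sequence(sample(0:1, 84, replace = TRUE), 17L, p)
  truth <- inner_decode(s, p)
  for (pos in 1:60) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(s, pos, pos))) {
      s2 <- s
      substr(s2, pos, pos) <- b
      d <- inner_decode(s2, p)
      expect_true(d$ok)
      expect_equal(d$index, truth$index)
      expect_equal(d$row, truth$row)
    }
  }
})

test_that("a single deletion with 3' fill is usually rejected (frameshift)", {
  p <- test_params()
  withr::local_seed(207)
  s <- assemble_sequence(sample(0:1, 84, replace = TRUE), 99L, p)
  outcomes <- logical(0)
  for (pos in 1:60) {
    for (fill in c("A", "C", "G", "T")) {
      s2 <- paste0(substr(s, 1, pos - 1), substr(s, pos + 1, 60), fill)
      d <- inner_decode(s2, p)
      outcomes <- c(outcomes, !d$ok | !identical(d$row, inner_decode(s, p)$row))
    }
  }
  expect_gt(mean(outcomes), 0.9)
})

test_that("encode_file emits N uniform 60-nt sequences with balanced GC", {
  p <- test_params()
  withr::local_seed(208)
  oligos <- encode_file(random_bytes(500), p)
  expect_s3_class(oligos, "oligo_set")
  expect_equal(nrow(oligos), p$N)
  expect_equal(unique(nchar(oligos$sequence)), 60L)
  expect_equal(oligos$index, 0:(p$N - 1))
  gc <- mean(gc_content(oligos$sequence))
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
})

test_that("randomization keeps per-oligo homopolymers short", {
  withr::local_seed(209)
  p <- test_params()
  meds <- vapply(1:20, function(i) {
    p2 <- code_params(N = p$N, K = p$K, scramble_seed = i)
    oligos <- encode_file(random_bytes(300), p2)
    stats::median(max_homopolymer(oligos$sequence))
  }, numeric(1))
  expect_true(all(meds <= 8))
})

test_that("noiseless encode/decode round-trips files of varied size", {
  p <- test_params()
  withr::local_seed(210)
  for (n in c(0, 1, 1000)) {
    b <- random_bytes(n)
    expect_identical(decode_oligos(encode_file(b, p), p), b)
  }
  # multi-block file
  p2 <- test_params(blocks = 3L)
  b <- random_bytes(5000)
  oligos <- encode_file(b, p2)
  expect_equal(nrow(oligos), 3L * p2$N)
  expect_identical(decode_oligos(oligos, p2), b)
})

test_that("outer decoding handles erasures and wrong rows within the radius", {
  p <- test_params()
  withr::local_seed(211)
  b <- random_bytes(800)
  oligos <- encode_file(b, p)
  table <- inner_decode(oligos$sequence, p)[, c("index", "row")]
  nk <- p$N - p$K # 84

  # pure erasures at the bound
  keep <- sort(sample(p$N, p$N - nk))
  res <- outer_decode(table[keep, ], p)
  expect_true(res$ok)
  expect_identical(res$bytes, b)
  expect_equal(res$n_erasures, nk)

  # mixed errors and erasures: 2e + eps <= nk
  e <- 20L
  eps <- 40L
  hit <- sample(p$N, e + eps)
  tbl <- table
  wrong <- paste(sample(0:1, 84, replace = TRUE), collapse = "")
  tbl$row[hit[seq_len(e)]] <- wrong
  tbl <- tbl[-hit[e + seq_len(eps)], ]
  res <- outer_decode(tbl, p)
  expect_true(res$ok)
  expect_identical(res$bytes, b)

  # beyond the bound: explicit failure, never silent corruption
  res_bad <- outer_decode(table[sort(sample(p$N, p$N - nk - 1)), ], p)
  expect_false(res_bad$ok)
  expect_null(res_bad$bytes)
  expect_false(any(res_bad$codewords$ok))
})
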