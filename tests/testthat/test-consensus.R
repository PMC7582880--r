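# Subsampling, alignment and weighted-majority consensus calling.

test_that("pairwise alignment reproduces the fixed scoring scheme", {
  a <- pairwise_align("ACGT", "ACGT")
  expect_equal(a$a, "ACGT")
  expect_equal(a$b, "ACGT")
  expect_equal(a$score, 4)

  a <- pairwise_align("ACGT", "AGT")
  expect_equal(a$score, 2) # 3 matches - 1 gap
  expect_equal(nchar(a$a), nchar(a$b))
  expect_equal(gsub("-", "", a$b), "AGT")
})

test_that("alignment scores match a brute-force enumeration oracle", {
  withr::local_seed(501)
  for (i in 1:100) {
    a <- random_dna(1, len = sample(2:8, 1))
    b <- random_dna(1, len = sample(2:8, 1))
    expect_equal(pairwise_align(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("cluster subsampling follows the 5/15/5x15 rule", {
  expect_equal(subsample_cluster(1:4), list())
  expect_equal(subsample_cluster(1:5), list(1:5))
  expect_equal(subsample_cluster(1:12), list(1:12))
  expect_equal(subsample_cluster(1:15), list(1:15))

  subs <- subsample_cluster(1:40, seed = 3)
  expect_length(subs, 5)
  for (s in subs) {
    expect_length(s, 15)
    expect_false(anyDuplicated(s) > 0)
    expect_true(all(s %in% 1:40))
  }
  expect_identical(subs, subsample_cluster(1:40, seed = 3))
})

test_that("center-star alignment preserves reads under gap removal", {
  r <- c("ACGTACGT", "ACGTACGT", "ACGTACGT", "ACGTACGT", "ACGACGT")
  m <- center_star_msa(r)
  expect_equal(nrow(m), 5)
  # removing gaps from row i recovers read i exactly
  for (i in seq_along(r)) {
    expect_equal(paste(m[i, m[i, ] != "-"], collapse = ""), r[i])
  }
  # the single-deletion read carries the only gap
  expect_equal(sum(m[5, ] == "-"), 1)
  expect_equal(sum(m[1:4, ] == "-"), 0)

  ident <- center_star_msa(rep("ACGTAC", 6))
  expect_true(all(ident != "-"))

  withr::local_seed(502)
  noisy <- corrupt_read(rep(random_dna(1), 8), channel_params(), seed = 1)
  mn <- center_star_msa(noisy)
  for (i in seq_along(noisy)) {
    expect_equal(paste(mn[i, mn[i, ] != "-"], collapse = ""), noisy[i])
  }
})

test_that("weighted majority scores bases at 1 and gaps at 0.4", {
  # score C = 2 beats gap score 3 * 0.4 = 1.2
  m <- matrix(c("C", "C", "-", "-", "-"), ncol = 1)
  expect_equal(weighted_majority(m, target_len = 1), "C")
  # exact tie 2.0 vs 2.0: the base wins
  m <- matrix(c("-", "-", "-", "-", "-", "A", "A"), ncol = 1)
  expect_equal(weighted_majority(m, target_len = 1), "A")
  # gap strictly ahead: column dropped, consensus too short -> reject
  m <- matrix(c("-", "-", "-", "A"), ncol = 1)
  expect_true(is.na(weighted_majority(m, target_len = 1)))
  # base tie broken A < C < G < T
  m <- matrix(c("G", "C", "C", "G"), ncol = 1)
  expect_equal(weighted_majority(m, target_len = 1), "C")
  # unanimous alignment returns the common read
  m <- center_star_msa(rep("ACGTACGT", 5))
  expect_equal(weighted_majority(m, target_len = 8), "ACGTACGT")
})

test_that("adding copies of the winning base never flips the call", {
  withr::local_seed(503)
  for (trial in 1:50) {
    col <- sample(c("A", "C", "G", "T", "-"), 9, replace = TRUE)
    m <- matrix(col, ncol = 1)
    call <- weighted_majority(m, target_len = NA)
    if (nchar(call) == 1) {
      m2 <- matrix(c(col, call), ncol = 1)
      expect_equal(weighted_majority(m2, target_len = NA), call)
    }
  }
})

test_that("consensus candidates beat raw reads by orders of magnitude", {
  withr::local_seed(504)
  p <- test_params()
  oligos <- encode_file(random_bytes(500), p)
  n_cl <- 60
  size <- 10
  src <- rep(seq_len(n_cl), each = size)
  reads <- corrupt_read(oligos$sequence[src], channel_params(), seed = 12)
  cl <- tibble::tibble(read_id = seq_along(reads), cluster = src)
  rt <- tibble::tibble(read_id = seq_along(reads), sequence = reads)

  cand <- consensus_candidates(rt, cl, seed = 13)
  frac_cand <- mean(cand$sequence == oligos$sequence[cand$cluster])
  # a raw read is error-free only when all three Poisson counts are zero
  p_read <- exp(-(7 + 2 + 3))
  expect_gte(frac_cand, 100 * p_read)
  expect_gte(frac_cand, 100 * mean(reads == oligos$sequence[src]))

  # clusters recovering their source through any candidate
  hit <- tapply(cand$sequence == oligos$sequence[cand$cluster],
                cand$cluster, any)
  expect_gte(mean(hit), 0.30)
})

test_that("candidate extraction respects cluster size filters", {
  withr::local_seed(505)
  oligo <- random_dna(1)
  reads <- corrupt_read(rep(oligo, 40), channel_params(), seed = 2)
  # 4-read cluster discarded; 40-read cluster subsampled into 5 subsets
  cl <- tibble::tibble(read_id = seq_len(44),
                       cluster = rep(c(1L, 2L), c(4L, 40L)))
  rt <- tibble::tibble(read_id = seq_len(44),
                       sequence = c(reads[1:4], reads))
  cand <- consensus_candidates(rt, cl, seed = 3)
  expect_false(1L %in% cand$cluster)
  expect_setequal(unique(cand$subsample[cand$cluster == 2L]), 1:5)
  expect_true(all(nchar(cand$sequence) == 60))
})
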