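# Prefix and MinHash/LSH clustering of noisy reads.

test_that("prefix clustering groups by exact 16-nt prefix", {
  reads <- c(a = "ACGTACGTACGTACGTAAAA",
             b = "ACGTACGTACGTACGTCCCC",  # differs at position 17+
             c = "TCGTACGTACGTACGTAAAA",  # differs at position 1
             d = "ACGTACGTACGTACGTAAAA",
             e = "ACG")                   # too short -> discard bin
  cl <- cluster_by_prefix(unname(reads))
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_equal(cl$cluster[1], cl$cluster[4])
  expect_false(cl$cluster[3] == cl$cluster[1])
  expect_true(is.na(cl$cluster[5]))
})

test_that("prefix clusters on simulated reads are pure but fragmented", {
  withr::local_seed(401)
  p <- code_params(N = 511, K = 343)
  oligos <- encode_file(random_bytes(2000), p)
  reads <- sample_reads(oligos[1:500, ], channel_params(coverage = 20),
                        seed = 7)
  cl <- cluster_by_prefix(trim_reads(reads))
  q <- cluster_quality(cl, reads, n_oligos = 500)
  expect_gte(q$purity, 0.95)
  expect_lt(q$frac_recoverable, 0.2) # one prefix error exiles a read
})

test_that("minhash signatures are deterministic and track Jaccard", {
  withr::local_seed(402)
  r <- random_dna(2, len = 60)
  s1 <- minhash_signature(r[1], k = 6, H = 128, seed = 1)
  s1b <- minhash_signature(r[1], k = 6, H = 128, seed = 1)
  expect_identical(s1, s1b)
  expect_identical(minhash_signature(c(r[1], r[1]), seed = 2)[1, ],
                   minhash_signature(c(r[1], r[1]), seed = 2)[2, ])

  # disjoint k-mer sets -> expected matching fraction ~ 0
  a <- strrep("A", 40)
  c_ <- strrep("C", 40)
  sc <- minhash_signature(c(a, c_), k = 6, H = 128, seed = 3)
  expect_equal(mean(sc[1, ] == sc[2, ]), 0)

  # overlapping reads: matching fraction estimates the true Jaccard
  x <- random_dna(1, len = 90)
  r1 <- substr(x, 1, 60)
  r2 <- substr(x, 21, 80)
  kmers <- function(s, k = 6) {
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  }
  j <- length(intersect(kmers(r1), kmers(r2))) /
    length(union(kmers(r1), kmers(r2)))
  sg <- minhash_signature(c(r1, r2), k = 6, H = 128, seed = 4)
  expect_equal(mean(sg[1, ] == sg[2, ]), j, tolerance = 0.1)

  # shorter than k -> NA sentinel row
  expect_true(all(is.na(minhash_signature("ACG", k = 6, H = 16, seed = 1))))
})

test_that("LSH clustering of noiseless duplicates is exact", {
  withr::local_seed(403)
  oligos <- random_dna(100)
  reads <- rep(oligos, each = 8)
  cl <- cluster_lsh(reads, seed = 5)
  expect_equal(dplyr::n_distinct(cl$cluster), 100L)
  expect_true(all(table(cl$cluster) == 8))
})

test_that("clustering is a partition and deterministic under a seed", {
  withr::local_seed(404)
  p <- test_params()
  oligos <- encode_file(random_bytes(300), p)
  reads <- sample_reads(oligos[1:150, ], channel_params(coverage = 15),
                        seed = 8)
  cl1 <- cluster_lsh(trim_reads(reads), seed = 9)
  cl2 <- cluster_lsh(trim_reads(reads), seed = 9)
  expect_identical(cl1, cl2)
  expect_equal(nrow(cl1), nrow(reads))
  expect_true(all(!is.na(cl1$cluster))) # all reads >= k nt here
})

test_that("LSH recovers more oligos than the prefix method, seed by seed", {
  withr::local_seed(405)
  p <- test_params()
  oligos <- encode_file(random_bytes(500), p)
  sub <- oligos[1:120, ]
  wins <- vapply(1:10, function(sd) {
    reads <- sample_reads(sub, channel_params(coverage = 20), seed = sd)
    tr <- trim_reads(reads)
    q_lsh <- cluster_quality(cluster_lsh(tr, seed = sd), reads,
                             n_oligos = 120)
    q_pre <- cluster_quality(cluster_by_prefix(tr), reads, n_oligos = 120)
    q_lsh$frac_recoverable >= q_pre$frac_recoverable
  }, logical(1))
  expect_true(all(wins))
})
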