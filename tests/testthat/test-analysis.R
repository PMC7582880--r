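# Read-profiling analytics: error classification, positional profiles,
# base composition, length and GC summaries.

test_that("error classification handles clean and single-error reads", {
  ref <- paste(rep(c("A", "C", "G", "T"), 15), collapse = "")
  expect_equal(nrow(classify_errors(ref, ref)), 0L)

  # deletion of reference position 10
  read_del <- paste0(substr(ref, 1, 9), substr(ref, 11, 60))
  ev <- classify_errors(read_del, ref)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$position, 10L)
  expect_equal(as.character(ev$type), "del")

  # substitution at position 25
  read_sub <- ref
  substr(read_sub, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                      substr(ref, 25, 25))[1]
  ev <- classify_errors(read_sub, ref)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$position, 25L)
  expect_equal(as.character(ev$type), "sub")

  # insertion between positions 30 and 31 is attributed to position 31
  read_ins <- paste0(substr(ref, 1, 30), "A", substr(ref, 31, 60))
  ev <- classify_errors(read_ins, ref)
  expect_equal(as.character(ev$type), "ins")
  expect_equal(ev$position, 31L)
})

test_that("injected error types are recovered in the 5' region", {
  withr::local_seed(701)
  refs <- random_dna(200)
  correct <- 0L
  total <- 0L
  for (r in refs) {
    pos <- sample(5:40, 1)
    type <- sample(c("del", "sub"), 1)
    read <- if (type == "del") {
      paste0(substr(r, 1, pos - 1), substr(r, pos + 1, 60))
    } else {
      r2 <- r
      substr(r2, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                      substr(r, pos, pos))[1]
      r2
    }
    ev <- classify_errors(read, r)
    total <- total + 1L
    if (nrow(ev) == 1 && as.character(ev$type) == type &&
        abs(ev$position - pos) <= 1) {
      correct <- correct + 1L
    }
  }
  expect_gte(correct / total, 0.9)
})

test_that("noiseless reads give an all-zero error profile", {
  p <- test_params()
  withr::local_seed(702)
  oligos <- encode_file(random_bytes(300), p)
  rs <- tibble::tibble(read_id = 1:50, sequence = oligos$sequence[1:50],
                       source = oligos$index[1:50])
  prof <- error_profile(rs, oligos)
  expect_true(all(prof$sub == 0))
  expect_true(all(prof$del == 0))
  expect_true(all(prof$ins == 0))
  expect_equal(attr(prof, "n_reads_used"), 50L)
})

test_that("the profile recovers simulator rates on the 5' half", {
  withr::local_seed(703)
  p <- test_params()
  oligos <- encode_file(random_bytes(300), p)
  reads <- sample_reads(oligos[1:60, ], channel_params(coverage = 40),
                        seed = 31)
  prof <- error_profile(reads, oligos)
  half <- prof$position <= 30
  expect_equal(mean(prof$del[half]), 7 / 60, tolerance = 0.02 / (7 / 60))
  expect_equal(mean(prof$sub[half]), 2 / 60, tolerance = 0.02 / (2 / 60))
  # apparent 3' inflation from the intruding tail
  late <- prof$position >= 55
  early <- prof$position <= 10
  expect_gt(mean(prof$sub[late] + prof$ins[late]),
            mean(prof$sub[early] + prof$ins[early]))
})

test_that("base composition is normalized and shows the index peak", {
  comp <- base_composition(rep(strrep("A", 60), 5))
  expect_true(all(comp$freq[comp$base == "A"] == 1))
  expect_true(all(comp$freq[comp$base != "A"] == 0))

  p <- test_params()
  withr::local_seed(704)
  oligos <- encode_file(random_bytes(500), p)
  comp <- base_composition(oligos)
  sums <- tapply(comp$freq, comp$position, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # constant ACAAC index prefix: A frequency 1 at positions 40, 42, 43
  a40 <- comp$freq[comp$position %in% c(40, 42, 43) & comp$base == "A"]
  expect_true(all(a40 == 1))
  c41 <- comp$freq[comp$position %in% c(41, 44) & comp$base == "C"]
  expect_true(all(c41 == 1))
  # payload positions are near-uniform
  u <- comp$freq[comp$position <= 39]
  expect_lt(max(abs(u - 0.25)), 0.1)
})

test_that("noisy reads blur the index peak and gain 3' C content", {
  p <- test_params()
  withr::local_seed(705)
  oligos <- encode_file(random_bytes(500), p)
  reads <- sample_reads(oligos, channel_params(coverage = 8), seed = 32)
  comp_design <- base_composition(oligos)
  comp_reads <- base_composition(trim_reads(reads))
  a42 <- function(cc) cc$freq[cc$position == 42 & cc$base == "A"]
  expect_lt(a42(comp_reads), a42(comp_design)) # peak attenuated
  c3p <- function(cc) mean(cc$freq[cc$position >= 57 & cc$base == "C"])
  expect_gt(c3p(comp_reads), c3p(comp_design) + 0.1) # C-rich tail visible
})

test_that("length histogram and GC content summarize read sets", {
  expect_equal(nrow(read_length_hist(character(0))), 0L)
  h <- read_length_hist(c("ACGT", "ACGTA", "ACGT"))
  expect_equal(h$n[h$length == 4], 2L)
  expect_equal(gc_content(c("GGCC", "ATAT", "GCAT")), c(1, 0, 0.5))

  withr::local_seed(706)
  p <- test_params()
  oligos <- encode_file(random_bytes(400), p)
  expect_equal(mean(gc_content(oligos)), 0.5, tolerance = 0.04)
  ch <- channel_params(window = Inf, tail = FALSE)
  reads <- corrupt_read(rep(oligos$sequence[1:50], 20), ch, seed = 33)
  h <- read_length_hist(reads)
  expect_equal(sum(h$length * h$n) / sum(h$n), 57, tolerance = 0.02)
})
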