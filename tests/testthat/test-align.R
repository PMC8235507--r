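test_that("exact substrings align perfectly on either strand", {
  ref <- test_ref()
  q <- substr(ref$seq, 101, 600)
  h <- local_align(q, ref)
  expect_identical(h$read_start, 0L)
  expect_identical(h$read_end, 500L)
  expect_identical(h$ref_start, 100L)
  expect_identical(h$ref_end, 600L)
  expect_identical(h$strand, "+")
  expect_identical(h$identity, 1)

  hm <- local_align(revcomp(q), ref)
  expect_identical(hm$ref_start, 100L)
  expect_identical(hm$ref_end, 600L)
  expect_identical(hm$strand, "-")
  expect_identical(hm$identity, 1)
})

test_that("uniform-random queries yield no qualifying segment", {
  ref <- test_ref()
  withr::with_seed(81, {
    for (i in 1:25) {
      q <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
      expect_null(local_align(q, ref))
    }
  })
})

test_that("alignment scores agree with an independent reference aligner", {
  ref <- test_ref()
  small <- substr(ref$seq, 1001, 1800)  # keep the oracle's quadratic DP fast
  withr::with_seed(82, {
    for (i in 1:12) {
      start <- sample(1:500, 1)
      q <- mutate_subs(substr(small, start, start + 299), 0.05)
      h <- local_align(q, small, align_params(min_identity = 0.6),
                       force_full = TRUE)
      expect_identical(as.numeric(h$score),
                       biostrings_local_score(q, small))
    }
  })
})

test_that("non-ACGT characters never match", {
  ref <- test_ref()
  q <- paste0(substr(ref$seq, 201, 500), strrep("N", 100))
  h <- local_align(q, ref)
  expect_identical(h$read_end, 300L)  # alignment stops before the Ns
  expect_identical(h$identity, 1)
})

test_that("segment chains recover the designed structures of error-free reads", {
  ref <- test_ref()
  # canonical: one plus-strand segment covering the read
  ch <- segment_read(ref$seq, ref, read_id = "can")
  expect_identical(nrow(ch), 1L)
  expect_identical(ch$strand, "+")
  expect_gte((ch$read_end - ch$read_start) / ch$read_length, 0.99)

  # 5'-SBG 800/800: two segments on the same left-anchored interval
  r <- withr::with_seed(1, simulate_snapback(ref, 5, 800, 800, strand = "+"))
  ch <- segment_read(r$seq, ref, read_id = "sbg")
  expect_identical(nrow(ch), 2L)
  expect_identical(ch$read_start, c(0L, 800L))
  expect_identical(ch$read_end, c(800L, 1600L))
  expect_identical(ch$ref_start, c(0L, 0L))
  expect_identical(ch$ref_end, c(800L, 800L))
  expect_identical(ch$strand, c("+", "-"))

  # GDM del [1000,3500): two collinear plus segments around the gap.
  # junction bases can match either side by chance, so boundaries may shift
  # by a few nt without changing the structure
  r <- withr::with_seed(2, simulate_gdm(ref, 1000, 3500, strand = "+"))
  ch <- segment_read(r$seq, ref, read_id = "gdm")
  expect_identical(nrow(ch), 2L)
  expect_identical(ch$ref_start[1], 0L)
  expect_identical(ch$ref_end[2], 4700L)
  expect_lt(abs(ch$ref_end[1] - 1000L), 5)
  expect_lt(abs(ch$ref_start[2] - 3500L), 5)
  expect_identical(unique(ch$strand), "+")

  # chains tile the read together with their uncovered intervals
  unc <- chain_uncovered(ch)
  covered <- sum(ch$read_end - ch$read_start) + sum(unc$end - unc$start)
  expect_identical(covered, ch$read_length[1])
})

test_that("segmentation is deterministic and coverage grows as identity drops", {
  ref <- test_ref()
  withr::with_seed(83, {
    reads <- simulate_population(ref, sim_config(n_reads = 30, seed = 84))
  })
  cov_at <- function(min_id) {
    vapply(reads$seq, function(s) {
      ch <- segment_read(s, ref, align_params(min_identity = min_id))
      sum(ch$read_end - ch$read_start)
    }, 1, USE.NAMES = FALSE)
  }
  c95 <- cov_at(0.95); c85 <- cov_at(0.85); c75 <- cov_at(0.75)
  expect_true(all(c85 >= c95))
  expect_true(all(c75 >= c85))
  ch1 <- segment_reads(reads, ref)
  ch2 <- segment_reads(reads, ref)
  expect_identical(ch1, ch2)
})

test_that("a long internal deletion is reported as two segments, not bridged", {
  ref <- test_ref()
  # deletion shorter than the flanking arms: a bridged alignment would score
  # higher than either arm alone, so the split must come from gap splitting
  r <- withr::with_seed(3, simulate_gdm(ref, 2000, 2300, strand = "+"))
  ch <- segment_read(r$seq, ref, read_id = "smalldel")
  expect_identical(nrow(ch), 2L)
  expect_lt(abs(ch$ref_end[1] - 2000L), 5)
  expect_lt(abs(ch$ref_start[2] - 2300L), 5)
  expect_equal(ch$ref_start[2] - ch$ref_end[1], 300L, tolerance = 0)
})
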