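fake_calls <- function(categories, subtypes = NULL, breakpoints = NULL,
                       loop_len = NULL, read_length = 2000L) {
  n <- length(categories)
  tibble::tibble(
    read_id = sprintf("r%d", seq_len(n)), read_length = read_length,
    category = categories,
    subtype = if (is.null(subtypes)) "NONE" else subtypes,
    strand = "+", itr5_intact = NA, itr3_intact = NA,
    fold_point_read = NA_integer_, arm_a = NA_integer_, arm_b = NA_integer_,
    loop_len = if (is.null(loop_len)) NA_integer_ else loop_len,
    breakpoint = if (is.null(breakpoints)) NA_integer_ else breakpoints,
    del_start = NA_integer_, del_end = NA_integer_,
    n_segments = 1L, n_gaps = 0L, note = NA_character_, annotation = "none")
}

test_that("population summaries count, fraction, and ratio correctly", {
  calls <- fake_calls(rep(c("CANONICAL", "SBG_5", "SBG_3", "ICG", "GDM",
                            "OTHER"), c(400, 150, 100, 200, 100, 50)))
  s <- summarize_population(calls)
  expect_identical(s$n_reads, 1000L)
  expect_identical(s$categories$n[match("CANONICAL", s$categories$category)],
                   400L)
  expect_equal(s$categories$fraction,
               c(0.4, 0.15, 0.1, 0.2, 0.1, 0.05)[
                 match(s$categories$category,
                       c("CANONICAL", "SBG_5", "SBG_3", "ICG", "GDM",
                         "OTHER"))])
  # ICG 200 vs SBG 250 reads -> ratio 0.8 in the ICG-vs-SBG orientation
  expect_identical(s$icg_sbg_ratio, 0.8)
  g <- glance(s)
  expect_identical(g$icg_count, 200L)
  expect_identical(g$sbg_count, 250L)
  t <- tidy(s)
  expect_identical(sum(t$n), 1000L)
})

test_that("summaries are invariant under read-order permutation", {
  calls <- noisy_population(1000)$calls
  s1 <- summarize_population(calls)
  s2 <- summarize_population(calls[sample(nrow(calls)), ])
  expect_equal(s1$categories, s2$categories)
  expect_equal(s1$icg_sbg_ratio, s2$icg_sbg_ratio)
})

test_that("run accounting sums the per-run manifests", {
  s <- summarize_population(fake_calls("CANONICAL"),
                            run_totals = c(run1 = 220645, run2 = 189274))
  expect_identical(s$run_totals$total, 409919)
  expect_identical(glance(s)$run_total, 409919L)
})

test_that("an extreme concentration of breakpoints gives the closed-form chi2", {
  # 1000 breakpoints in one of 20 equal bins: X2 = 950^2/50 + 19 * 50 = 19000
  rng <- c(144, 4556)
  bp <- rep(rng[1] + 10, 1000)
  u <- breakpoint_uniformity_test(bp, rng, n_bins = 20)
  expect_equal(unname(u$statistic), 19000)
  expect_identical(unname(u$parameter), 19L)
  expect_lt(u$p.value, 1e-300)
})

test_that("exactly uniform counts give chi2 = 0 and p = 1", {
  rng <- c(0, 2000)
  bp <- rep(seq(50, 1950, by = 100), each = 10)  # 10 per each of 20 bins
  u <- breakpoint_uniformity_test(bp, rng, n_bins = 20)
  expect_equal(unname(u$statistic), 0)
  expect_equal(u$p.value, 1)
})

test_that("under-filled bins are merged and tiny samples error out", {
  rng <- c(0, 2000)
  withr::with_seed(101, {
    u <- breakpoint_uniformity_test(runif(60, 0, 2000), rng, n_bins = 20)
  })
  # 60 points over 20 bins -> expected 3 < 5, so bins must have been merged
  expect_lt(unname(u$parameter), 19L)
  expect_true(all(u$expected >= 5))
  expect_error(breakpoint_uniformity_test(runif(5, 0, 2000), rng), "too few")
})

test_that("the chi-square p agrees with a likelihood-ratio G-test", {
  rng <- c(144, 4556)
  withr::with_seed(102, {
    bp <- runif(1000, rng[1], rng[2])
  })
  u <- breakpoint_uniformity_test(bp, rng, n_bins = 20)
  obs <- u$observed; ex <- u$expected
  g <- 2 * sum(ifelse(obs > 0, obs * log(obs / ex), 0))
  p_g <- pchisq(g, unname(u$parameter), lower.tail = FALSE)
  # both tests are asymptotically equivalent: p within one order of magnitude
  expect_lt(abs(log10(u$p.value) - log10(p_g)), 1)
})

test_that("the arm-symmetry histogram conserves SBG counts", {
  calls <- fake_calls(rep(c("SBG_5", "SBG_3", "ICG"), c(30, 20, 10)),
                      loop_len = c(rep(0L, 25), rep(150L, 25), rep(NA, 10)))
  h <- arm_symmetry_histogram(calls, bin_width = 100)
  expect_identical(sum(h$count), 50L)
  expect_identical(h$count[h$loop_lo == 0], 25L)
  expect_identical(nrow(arm_symmetry_histogram(fake_calls("ICG"))), 0L)
  # simulated geometric loops: histogram mean close to the draw mean
  loops <- withr::with_seed(103, rgeom(2000, 1 / 300) + 1L)
  calls <- fake_calls(rep("SBG_5", 2000), loop_len = loops)
  h <- arm_symmetry_histogram(calls, bin_width = 50)
  mids <- (h$loop_lo + h$loop_hi) / 2
  est <- sum(mids * h$count) / sum(h$count)
  expect_lt(abs(est - 300), 3 * 300 / sqrt(2000) + 25)  # 3 sigma + bin width/2
})
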