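test_that("error-free payloads reconstruct exactly from their truth records", {
  ref <- test_ref()
  L <- ref$length
  withr::with_seed(11, {
    r <- simulate_canonical(ref, strand = "+")
    expect_identical(r$seq, ref$seq)
    r <- simulate_canonical(ref, strand = "-")
    expect_identical(r$seq, revcomp(ref$seq))

    r <- simulate_snapback(ref, 5, 800, 600, strand = "+")
    expect_identical(r$seq, paste0(substr(ref$seq, 1, 800),
                                   revcomp(substr(ref$seq, 1, 600))))
    expect_identical(r$subtype, "ASYMMETRIC")
    expect_identical(nchar(r$seq), 1400L)

    r <- simulate_snapback(ref, 3, 1000, 1000, strand = "+")
    expect_identical(r$seq, paste0(revcomp(substr(ref$seq, L - 999, L)),
                                   substr(ref$seq, L - 999, L)))
    expect_identical(r$subtype, "SYMMETRIC")

    r <- simulate_icg(ref, breakpoint = 2000, strand = "+")
    expect_identical(r$seq, substr(ref$seq, 2001, L))
    expect_identical(nchar(r$seq), L - 2000L)

    r <- simulate_gdm(ref, 1000, 3500, strand = "+")
    expect_identical(r$seq, paste0(substr(ref$seq, 1, 1000),
                                   substr(ref$seq, 3501, L)))
    expect_identical(nchar(r$seq), 1000L + (L - 3500L))
  })
})

test_that("symmetric snapback reads fold onto the same reference interval", {
  ref <- test_ref()
  r <- withr::with_seed(1, simulate_snapback(ref, 5, 800, 800, strand = "+"))
  expect_identical(nchar(r$seq), 1600L)
  expect_identical(substr(r$seq, 1, 800), revcomp(substr(r$seq, 801, 1600)))
})

test_that("invalid simulation coordinates are rejected", {
  ref <- test_ref()
  expect_error(simulate_icg(ref, breakpoint = 50), "ITR")
  expect_error(simulate_icg(ref, breakpoint = 4690), "ITR")
  expect_error(simulate_gdm(ref, 100, 500), "ITR")
  expect_error(simulate_gdm(ref, 3500, 1000), "del_start")
  expect_error(simulate_snapback(ref, 5, 0, 100), "arms")
  expect_error(simulate_snapback(ref, 4, 100, 100), "side")
  expect_error(simulate_other(0), "length")
})

test_that("canonical strands are drawn evenly when unspecified", {
  ref <- test_ref()
  strands <- withr::with_seed(21, {
    vapply(1:2000, function(i) simulate_canonical(ref)$strand, "")
  })
  phat <- mean(strands == "+")
  # 3 sigma binomial band around 0.5 at n = 2000
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("the error model is a no-op at zero rates and binomial otherwise", {
  s <- strrep("ACGT", 2500)  # 10 kb
  expect_identical(apply_errors(s, 0, 0, 0), s)
  subs <- withr::with_seed(31, {
    vapply(1:50, function(i) {
      out <- apply_errors(s, sub_rate = 0.01, ins_rate = 0, del_rate = 0)
      sum(strsplit(out, "")[[1]] != strsplit(s, "")[[1]])
    }, 1)
  })
  # mean substitutions n*p = 100, 3 sigma over 50 replicates
  expect_lt(abs(mean(subs) - 100), 3 * sqrt(100 * 0.99 / 50))
  lens <- withr::with_seed(32, {
    vapply(1:30, function(i)
      nchar(apply_errors(s, 0, ins_rate = 0.001, del_rate = 0.01)), 1)
  })
  expect_lt(mean(lens), nchar(s))  # net deletion pressure shortens reads
  expect_error(apply_errors(s, sub_rate = 0.5), "rates")
})

test_that("quota populations hit exact category counts and are reproducible", {
  ref <- test_ref()
  cfg <- sim_config(n_reads = 200, seed = 41)
  reads <- simulate_population(ref, cfg)
  cnt <- table(reads$category)
  expect_identical(as.integer(cnt[c("CANONICAL", "SBG_5", "SBG_3", "ICG",
                                    "GDM", "OTHER")]),
                   c(80L, 30L, 20L, 40L, 20L, 10L))
  expect_identical(nrow(reads), 200L)
  reads2 <- simulate_population(ref, cfg)
  expect_identical(reads, reads2)
  expect_error(sim_config(proportions = c(CANONICAL = 0.9, SBG_5 = 0.2,
                                          SBG_3 = 0, ICG = 0, GDM = 0,
                                          OTHER = 0)), "sum to 1")
})

test_that("category payload lengths obey their closed-form formulas", {
  ref <- test_ref()
  L <- ref$length
  reads <- errorfree_population(1000)$reads
  len <- nchar(reads$seq)
  sbg <- reads$category %in% c("SBG_5", "SBG_3")
  expect_identical(len[sbg], as.integer(reads$arm_a + reads$arm_b)[sbg])
  icg <- reads$category == "ICG"
  expect_identical(len[icg], as.integer(L - reads$breakpoint)[icg])
  gdm <- reads$category == "GDM"
  expect_identical(len[gdm],
                   as.integer(L - (reads$del_end - reads$del_start))[gdm])
  can <- reads$category == "CANONICAL"
  expect_true(all(len[can] == L))
})

test_that("population truth proportions converge at large n (multinomial mode)", {
  ref <- test_ref()
  cfg <- sim_config(n_reads = 10000, quota = FALSE, seed = 51,
                    sub_rate = 0, ins_rate = 0, del_rate = 0)
  reads <- simulate_population(ref, cfg)
  frac <- prop.table(table(reads$category))
  for (cat in names(cfg$proportions)) {
    p <- cfg$proportions[[cat]]
    expect_lt(abs(frac[[cat]] - p), 3 * sqrt(p * (1 - p) / 10000))
  }
})

test_that("reads round-trip through FASTQ + sidecar and FASTQ is byte-stable", {
  ref <- test_ref()
  reads <- simulate_population(ref, sim_config(n_reads = 20, seed = 61))
  dir <- withr::local_tempdir()
  p1 <- write_reads(reads, file.path(dir, "a"))
  p2 <- write_reads(reads, file.path(dir, "b"))
  expect_identical(readLines(p1[["fastq"]]), readLines(p2[["fastq"]]))
  back <- read_reads(p1[["fastq"]], p1[["meta"]])
  expect_identical(back$id, reads$id)
  expect_identical(back$seq, reads$seq)
  expect_identical(back$n_passes, reads$n_passes)
  truth <- readr::read_tsv(p1[["truth"]], comment = "#",
                           show_col_types = FALSE)
  expect_identical(nrow(truth), nrow(reads))
})
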