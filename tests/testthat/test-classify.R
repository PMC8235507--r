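mk_chain <- function(read_len, ...) {
  rows <- list(...)
  tibble::tibble(
    read_id = "t", read_length = as.integer(read_len),
    read_start = as.integer(sapply(rows, `[[`, 1)),
    read_end = as.integer(sapply(rows, `[[`, 2)),
    ref_start = as.integer(sapply(rows, `[[`, 3)),
    ref_end = as.integer(sapply(rows, `[[`, 4)),
    strand = as.character(sapply(rows, `[[`, 5)),
    identity = 1, score = 1L)
}

test_that("the decision tree reproduces the canonical taxonomy on ideal chains", {
  ref <- test_ref()
  # full-length cover -> CANONICAL
  call <- classify_read(mk_chain(4700, list(0, 4700, 0, 4700, "+")), ref)
  expect_identical(call$category, "CANONICAL")
  expect_true(call$itr5_intact && call$itr3_intact)

  # left-anchored opposite-strand pair -> 5'-SBG, symmetric
  call <- classify_read(mk_chain(1600, list(0, 800, 0, 800, "+"),
                                 list(800, 1600, 0, 800, "-")), ref)
  expect_identical(call$category, "SBG_5")
  expect_identical(call$subtype, "SYMMETRIC")
  expect_identical(call$fold_point_read, 800L)
  expect_identical(c(call$arm_a, call$arm_b), c(800L, 800L))
  expect_match(call$annotation, "dsRNA")

  # right-terminal single segment -> ICG with the 3' ITR and breakpoint
  call <- classify_read(mk_chain(2700, list(0, 2700, 2000, 4700, "+")), ref)
  expect_identical(call$category, "ICG")
  expect_true(call$itr3_intact)
  expect_false(call$itr5_intact)
  expect_identical(call$breakpoint, 2000L)

  # two collinear plus segments with a large gap -> GDM
  call <- classify_read(mk_chain(2200, list(0, 1000, 0, 1000, "+"),
                                 list(1000, 2200, 3500, 4700, "+")), ref)
  expect_identical(call$category, "GDM")
  expect_identical(c(call$del_start, call$del_end), c(1000L, 3500L))

  # empty chain -> OTHER
  call <- classify_read(mk_chain(100)[0, ], ref, read_id = "x",
                        read_length = 100)
  expect_identical(call$category, "OTHER")
})

test_that("fold-point detection demands opposite strands at one terminus", {
  ref <- test_ref()
  p <- classify_params()
  # junction gap within tolerance: arms measured on the reference
  ch <- mk_chain(1450, list(0, 800, 0, 800, "+"), list(850, 1450, 0, 600, "-"))
  f <- find_fold_point(ch, ref$length, p)
  expect_identical(c(f$arm_a, f$arm_b), c(800L, 600L))
  expect_identical(f$side, 5L)
  # same-strand collinear pair is a deletion pattern, not a fold
  ch <- mk_chain(2200, list(0, 1000, 0, 1000, "+"),
                 list(1000, 2200, 3500, 4700, "+"))
  expect_null(find_fold_point(ch, ref$length, p))
  # right-terminal fold -> side 3
  ch <- mk_chain(1800, list(0, 900, 3800, 4700, "-"),
                 list(900, 1800, 3800, 4700, "+"))
  f <- find_fold_point(ch, ref$length, p)
  expect_identical(f$side, 3L)
})

test_that("ITR coverage uses the covered fraction of the ITR interval", {
  ref <- test_ref()
  # 140 of 144 nt covered is intact at the default 0.9 fraction
  ch <- mk_chain(200, list(0, 140, 0, 140, "+"))
  expect_true(detect_itr_coverage(ch, ref)[["itr5"]])
  ch <- mk_chain(200, list(0, 100, 0, 100, "+"))
  expect_false(detect_itr_coverage(ch, ref)[["itr5"]])
})

test_that("regulatory annotation follows promoter content of the fold", {
  ref <- test_ref()
  # long 3' arms reach back across P40 (at ~0.38 of the genome)
  r3 <- withr::with_seed(4, simulate_snapback(ref, 3, 3100, 3100, strand = "+"))
  call <- classify_reads(r3 |> dplyr::mutate(id = "d3"), ref)
  expect_identical(call$category, "SBG_3")
  expect_match(call$annotation, "double-enhancer")
  # short 3' arms do not span P40: no annotation
  r3s <- withr::with_seed(5, simulate_snapback(ref, 3, 900, 900, strand = "+"))
  call <- classify_reads(r3s |> dplyr::mutate(id = "d3s"), ref)
  expect_identical(call$category, "SBG_3")
  expect_identical(call$annotation, "none")
  # canonical reads carry no annotation
  can <- classify_read(mk_chain(4700, list(0, 4700, 0, 4700, "+")), ref)
  expect_identical(can$annotation, "none")
})

test_that("classification is invariant to reverse-complementing the read", {
  ref <- test_ref()
  withr::with_seed(91, {
    probes <- list(
      simulate_snapback(ref, 5, 900, 650, strand = "+"),
      simulate_icg(ref, breakpoint = 1500, strand = "+"),
      simulate_gdm(ref, 800, 3900, strand = "+"),
      simulate_canonical(ref, strand = "+"))
  })
  for (r in probes) {
    fwd <- classify_read(segment_read(r$seq, ref), ref,
                         read_id = "f", read_length = nchar(r$seq))
    rev <- classify_read(segment_read(revcomp(r$seq), ref), ref,
                         read_id = "r", read_length = nchar(r$seq))
    expect_identical(rev$category, fwd$category)
    expect_identical(rev$subtype, fwd$subtype)
    if (!is.na(fwd$strand)) {
      expect_identical(rev$strand, setdiff(c("+", "-"), fwd$strand))
    }
  }
})

test_that("every read receives exactly one category and counts are conserved", {
  pop <- noisy_population(1000)
  calls <- pop$calls
  expect_identical(nrow(calls), 1000L)
  expect_false(any(is.na(calls$category)))
  expect_identical(sum(table(calls$category)), 1000L)
  expect_identical(sort(calls$read_id), sort(pop$reads$id))
})

test_that("subtype calls agree with truth away from the symmetry threshold", {
  ref <- test_ref()
  pop <- noisy_population(1000)
  joined <- dplyr::inner_join(
    dplyr::select(pop$reads, read_id = "id", truth_sub = "subtype",
                  "arm_a", "arm_b", truth_cat = "category"),
    dplyr::select(pop$calls, "read_id", called_sub = "subtype",
                  called_cat = "category"),
    by = "read_id") |>
    dplyr::filter(.data$truth_cat %in% c("SBG_5", "SBG_3"),
                  .data$called_cat == .data$truth_cat,
                  abs(abs(.data$arm_a - .data$arm_b) - 100) >= 100)
  expect_gt(nrow(joined), 50)
  expect_identical(joined$called_sub, joined$truth_sub)
})
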