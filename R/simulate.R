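CATEGORIES <- c("CANONICAL", "SBG_5", "SBG_3", "ICG", "GDM", "OTHER")

sim_read_row <- function(seq, category, subtype = "NONE", strand = NA_character_,
                         arm_a = NA_integer_, arm_b = NA_integer_,
                         breakpoint = NA_integer_, del_start = NA_integer_,
                         del_end = NA_integer_) {
  tibble::tibble(
    id = NA_character_, seq = seq,
    n_passes = NA_integer_, predicted_accuracy = NA_real_,
    category = category, subtype = subtype, strand = strand,
    arm_a = as.integer(arm_a), arm_b = as.integer(arm_b),
    breakpoint = as.integer(breakpoint),
    del_start = as.integer(del_start), del_end = as.integer(del_end)
  )
}

pick_strand <- function(strand) {
  if (is.null(strand) || is.na(strand)) sample(c("+", "-"), 1) else strand
}

#' Simulate a canonical full-length genome read
#'
#' The error-free payload is the full reference sequence (plus strand) or its
#' reverse complement (minus strand); both strands are packaged equally, so
#' an unspecified strand is drawn 50/50.
#'
#' @param ref An `aav_reference`.
#' @param strand `"+"`, `"-"`, or `NULL` to draw at random.
#' @return One-row reads tibble with truth columns.
#' @export
simulate_canonical <- function(ref, strand = NULL) {
  strand <- pick_strand(strand)
  s <- if (strand == "+") ref$seq else revcomp(ref$seq)
  sim_read_row(s, "CANONICAL", strand = strand)
}

#' Simulate a snapback-genome (SBG) read
#'
#' A snapback genome is the covalent single strand of a fold-back molecule:
#' one genome moiety followed by the reverse complement of a (possibly
#' different-length) overlapping moiety. A 5'-SBG folds over the left
#' terminus (both arms are genome prefixes); a 3'-SBG over the right terminus
#' (both arms are suffixes). Unequal arms leave a single-stranded loop of
#' `|arm_a - arm_b|` nt.
#'
#' @param ref An `aav_reference`.
#' @param side 5 or 3: which terminus the molecule folds over.
#' @param arm_a,arm_b Arm lengths in nt (each <= genome length).
#' @param strand `"+"` emits the arm-a-first strand; `"-"` its reverse
#'   complement.
#' @param sym_tol Arm-length difference (nt) at or below which the truth
#'   subtype is SYMMETRIC. Default 100.
#' @return One-row reads tibble with truth columns.
#' @export
simulate_snapback <- function(ref, side, arm_a, arm_b, strand = NULL,
                              sym_tol = 100) {
  side <- as.integer(side)
  if (!side %in% c(5L, 3L)) stop("side must be 5 or 3")
  if (arm_a < 1 || arm_b < 1 || arm_a > ref$length || arm_b > ref$length) {
    stop("SBG arms must be in [1, genome length]")
  }
  strand <- pick_strand(strand)
  L <- ref$length
  s <- if (side == 5L) {
    paste0(substr(ref$seq, 1, arm_a), revcomp(substr(ref$seq, 1, arm_b)))
  } else {
    paste0(revcomp(substr(ref$seq, L - arm_a + 1, L)),
           substr(ref$seq, L - arm_b + 1, L))
  }
  if (strand == "-") s <- revcomp(s)
  sim_read_row(s, if (side == 5L) "SBG_5" else "SBG_3",
               subtype = if (abs(arm_a - arm_b) <= sym_tol) "SYMMETRIC" else "ASYMMETRIC",
               strand = strand, arm_a = arm_a, arm_b = arm_b)
}

#' Simulate an incomplete-genome (ICG) read
#'
#' An ICG retains one intact terminal ITR and a partial coding sequence that
#' never reaches the opposite ITR (aborted packaging). Reads are anchored at
#' the right terminus in plus-strand coordinates: the error-free payload is
#' `ref.seq[breakpoint:L]`, or its reverse complement on the minus strand.
#' An unspecified breakpoint is drawn uniformly over the non-ITR interior.
#'
#' @param ref An `aav_reference`.
#' @param breakpoint 0-based reference coordinate strictly inside the
#'   interior, or `NULL` to draw uniformly.
#' @param strand `"+"`, `"-"`, or `NULL` to draw 50/50.
#' @return One-row reads tibble with truth columns.
#' @export
simulate_icg <- function(ref, breakpoint = NULL, strand = NULL) {
  interior <- ref_interior(ref)
  if (is.null(breakpoint)) {
    breakpoint <- sample(seq.int(interior[1] + 1L, interior[2] - 1L), 1)
  }
  if (breakpoint <= interior[1] || breakpoint >= interior[2]) {
    stop("ICG breakpoint ", breakpoint, " lies inside an ITR (interior is (",
         interior[1], ", ", interior[2], "))")
  }
  strand <- pick_strand(strand)
  s <- substr(ref$seq, breakpoint + 1, ref$length)
  if (strand == "-") s <- revcomp(s)
  sim_read_row(s, "ICG", strand = strand, breakpoint = breakpoint)
}

#' Simulate a genome-deletion-mutant (GDM) read
#'
#' A GDM retains both terminal ITRs but is missing an internal region: the
#' error-free payload is `ref.seq[0:del_start] ++ ref.seq[del_end:L]`.
#'
#' @param ref An `aav_reference`.
#' @param del_start,del_end 0-based half-open deletion interval, fully inside
#'   the non-ITR interior.
#' @param strand `"+"`, `"-"`, or `NULL` to draw 50/50.
#' @return One-row reads tibble with truth columns.
#' @export
simulate_gdm <- function(ref, del_start, del_end, strand = NULL) {
  interior <- ref_interior(ref)
  if (del_start >= del_end) stop("del_start must be < del_end")
  if (del_start < interior[1] || del_end > interior[2]) {
    stop("GDM deletion [", del_start, ", ", del_end,
         ") overlaps an ITR (interior is [", interior[1], ", ", interior[2], "))")
  }
  strand <- pick_strand(strand)
  s <- paste0(substr(ref$seq, 1, del_start),
              substr(ref$seq, del_end + 1, ref$length))
  if (strand == "-") s <- revcomp(s)
  sim_read_row(s, "GDM", strand = strand,
               del_start = del_start, del_end = del_end)
}

#' Simulate a foreign-DNA read
#'
#' Uniform-random DNA unrelated to the reference, standing in for particles
#' that packaged host or helper DNA.
#'
#' @param length Read length in nt (> 0).
#' @return One-row reads tibble with truth columns.
#' @export
simulate_other <- function(length) {
  if (length < 1) stop("read length must be > 0")
  sim_read_row(random_dna(length), "OTHER")
}

#' Apply a residual sequencing-error model
#'
#' Independent per-base substitution, insertion (after the base), and
#' deletion at the given rates; emulates the small residual error of
#' consensus reads that already passed an accuracy gate.
#'
#' @param seq Character vector of DNA sequences.
#' @param sub_rate,ins_rate,del_rate Per-base rates, each in \[0, 0.2\].
#' @return Character vector of mutated sequences.
#' @export
apply_errors <- function(seq, sub_rate = 0.003, ins_rate = 0.001,
                         del_rate = 0.001) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 0.2)) stop("error rates must be in [0, 0.2]")
  if (all(rates == 0)) return(seq)
  vapply(seq, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(b)
    del <- stats::runif(n) < del_rate
    sub <- stats::runif(n) < sub_rate
    ins <- stats::runif(n) < ins_rate
    if (any(sub)) {
      b[sub] <- vapply(b[sub], function(x) sample(setdiff(BASES, x), 1), "")
    }
    out <- b
    if (any(ins)) out[ins] <- paste0(out[ins], sample(BASES, sum(ins), TRUE))
    if (any(del)) out[del] <- substring(out[del], 2)  # drop base, keep insertion
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulation configuration for a mixed virion population
#'
#' Defaults emulate a mixed wild-type-like particle population containing
#' every configuration class, with residual error rates consistent with a
#' 0.99 predicted-accuracy consensus gate. Category proportions are
#' illustrative (the source populations are not quantified), chosen so every
#' class is well represented.
#'
#' @param n_reads Number of reads.
#' @param proportions Named fractions over
#'   `CANONICAL, SBG_5, SBG_3, ICG, GDM, OTHER`; must sum to 1.
#' @param sub_rate,ins_rate,del_rate Residual per-base error rates.
#' @param arm_min,arm_max SBG arm-length range (nt); `arm_max = NULL` means
#'   half the genome, keeping 5' arms in the left moiety and 3' arms in the
#'   right moiety.
#' @param sym_frac Fraction of SBGs drawn from the symmetric branch.
#' @param sym_tol Arm-difference threshold (nt) for SYMMETRIC truth labels.
#' @param loop_mean Mean of the geometric loop-length draw for asymmetric
#'   SBGs.
#' @param del_min Minimum GDM deletion length (nt).
#' @param del_margin Minimum distance (nt) of a GDM deletion from each ITR.
#' @param other_len_range Length range of foreign-DNA reads.
#' @param qc_fail_frac Fraction of reads given metadata that fails the
#'   default QC gate.
#' @param quota If `TRUE`, category counts are exact quotas (largest
#'   remainder); otherwise a multinomial draw.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 1000,
                       proportions = c(CANONICAL = 0.4, SBG_5 = 0.15,
                                       SBG_3 = 0.1, ICG = 0.2, GDM = 0.1,
                                       OTHER = 0.05),
                       sub_rate = 0.003, ins_rate = 0.001, del_rate = 0.001,
                       arm_min = 300, arm_max = NULL, sym_frac = 0.5,
                       sym_tol = 100, loop_mean = 300,
                       del_min = 200, del_margin = 200,
                       other_len_range = c(500, 4000),
                       qc_fail_frac = 0.1, quota = TRUE, seed = 1) {
  if (!setequal(names(proportions), CATEGORIES)) {
    stop("proportions must be named over: ", paste(CATEGORIES, collapse = ", "))
  }
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (any(c(sub_rate, ins_rate, del_rate) < 0) ||
      any(c(sub_rate, ins_rate, del_rate) > 0.2)) {
    stop("error rates must be in [0, 0.2]")
  }
  structure(
    list(n_reads = as.integer(n_reads),
         proportions = proportions[CATEGORIES],
         sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
         arm_min = arm_min, arm_max = arm_max, sym_frac = sym_frac,
         sym_tol = sym_tol, loop_mean = loop_mean,
         del_min = del_min, del_margin = del_margin,
         other_len_range = other_len_range,
         qc_fail_frac = qc_fail_frac, quota = quota, seed = seed),
    class = "sim_config"
  )
}

# quota counts by largest remainder, deterministic
quota_counts <- function(n, p) {
  raw <- n * p
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

draw_sbg_arms <- function(ref, config) {
  arm_max <- if (is.null(config$arm_max)) floor(ref$length / 2) else config$arm_max
  a <- sample(seq.int(config$arm_min, arm_max), 1)
  if (stats::runif(1) < config$sym_frac) {
    d <- round(abs(stats::rnorm(1, 0, config$sym_tol / 4)))
    d <- min(d, config$sym_tol)
  } else {
    d <- stats::rgeom(1, 1 / config$loop_mean) + 1L
  }
  sgn <- sample(c(-1L, 1L), 1)
  b <- a + sgn * d
  if (b < config$arm_min || b > arm_max) b <- a - sgn * d
  b <- min(max(b, config$arm_min), arm_max)
  c(a, b)
}

#' Simulate a mixed single-molecule read population
#'
#' Draws category labels (quota or multinomial), builds each read's
#' error-free payload from its truth record, applies the residual error
#' model, and attaches consensus-read metadata (`n_passes`,
#' `predicted_accuracy`) such that roughly `qc_fail_frac` of reads fail the
#' default QC gate. Deterministic for a fixed config seed.
#'
#' @param ref An `aav_reference`.
#' @param config A [sim_config()].
#' @return A reads tibble: `id seq n_passes predicted_accuracy` plus truth
#'   columns `category subtype strand arm_a arm_b breakpoint del_start
#'   del_end`.
#' @examples
#' ref <- build_reference()
#' reads <- simulate_population(ref, sim_config(n_reads = 20, seed = 7))
#' dplyr::count(reads, category)
#' @export
simulate_population <- function(ref, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  interior <- ref_interior(ref)
  withr::with_seed(config$seed, {
    cats <- if (config$quota) {
      rep(CATEGORIES, quota_counts(config$n_reads, config$proportions))
    } else {
      sample(CATEGORIES, config$n_reads, replace = TRUE,
             prob = config$proportions)
    }
    cats <- sample(cats)  # shuffle emission order
    rows <- lapply(cats, function(cat) {
      switch(cat,
        CANONICAL = simulate_canonical(ref),
        SBG_5 = {
          arms <- draw_sbg_arms(ref, config)
          simulate_snapback(ref, 5, arms[1], arms[2], strand = NULL,
                            sym_tol = config$sym_tol)
        },
        SBG_3 = {
          arms <- draw_sbg_arms(ref, config)
          simulate_snapback(ref, 3, arms[1], arms[2], strand = NULL,
                            sym_tol = config$sym_tol)
        },
        ICG = simulate_icg(ref),
        GDM = {
          lo <- interior[1] + config$del_margin
          hi <- interior[2] - config$del_margin
          len <- sample(seq.int(config$del_min, max(config$del_min, hi - lo - 1)), 1)
          ds <- sample(seq.int(lo, hi - len), 1)
          simulate_gdm(ref, ds, ds + len)
        },
        OTHER = simulate_other(sample(seq.int(config$other_len_range[1],
                                              config$other_len_range[2]), 1))
      )
    })
    reads <- dplyr::bind_rows(rows)
    n <- nrow(reads)
    reads$id <- sprintf("read_%06d", seq_len(n))
    if (any(c(config$sub_rate, config$ins_rate, config$del_rate) > 0)) {
      reads$seq <- apply_errors(reads$seq, config$sub_rate, config$ins_rate,
                                config$del_rate)
    }
    fails <- stats::runif(n) < config$qc_fail_frac
    fail_mode <- sample(c("passes", "accuracy"), n, replace = TRUE)
    reads$n_passes <- 3L + stats::rpois(n, 7)
    reads$predicted_accuracy <- round(stats::runif(n, 0.99, 0.9995), 4)
    low_p <- fails & fail_mode == "passes"
    low_a <- fails & fail_mode == "accuracy"
    reads$n_passes[low_p] <- sample(1:2, sum(low_p), replace = TRUE)
    reads$predicted_accuracy[low_a] <-
      round(stats::runif(sum(low_a), 0.95, 0.9899), 4)
    reads
  })
}

#' Write reads to FASTQ with sidecar metadata and truth tables
#'
#' Emits `<prefix>.fastq` (fixed placeholder qualities),
#' `<prefix>.meta.tsv` (`read_id n_passes predicted_accuracy`) and, when
#' truth columns are present, `<prefix>.truth.tsv`.
#'
#' @param reads A reads tibble.
#' @param prefix Output path prefix.
#' @param seed Seed recorded in the provenance headers.
#' @return Named character vector of written paths, invisibly.
#' @export
write_reads <- function(reads, prefix, seed = NULL) {
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$id
  fq <- paste0(prefix, ".fastq")
  q <- Biostrings::BStringSet(vapply(Biostrings::width(s), function(w)
    strrep("I", w), ""))
  Biostrings::writeXStringSet(s, fq, format = "fastq", qualities = q)
  meta <- paste0(prefix, ".meta.tsv")
  hdr <- provenance_header(seed)
  writeLines(hdr, meta)
  readr::write_tsv(
    dplyr::select(dplyr::rename(reads, read_id = "id"), "read_id",
                  "n_passes", "predicted_accuracy"),
    meta, append = TRUE, col_names = TRUE)
  paths <- c(fastq = fq, meta = meta)
  if ("category" %in% names(reads)) {
    truth <- paste0(prefix, ".truth.tsv")
    writeLines(hdr, truth)
    readr::write_tsv(
      dplyr::select(dplyr::rename(reads, read_id = "id"), "read_id",
                    "category", "subtype", "strand", "arm_a", "arm_b",
                    "breakpoint", "del_start", "del_end"),
      truth, append = TRUE, col_names = TRUE)
    paths <- c(paths, truth = truth)
  }
  invisible(paths)
}

#' Read a FASTQ read set with optional sidecar metadata
#'
#' @param fastq Path to a FASTQ file.
#' @param meta Optional sidecar TSV (`read_id n_passes predicted_accuracy`).
#' @return A reads tibble (`id seq n_passes predicted_accuracy`).
#' @export
read_reads <- function(fastq, meta = NULL) {
  s <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  reads <- tibble::tibble(id = names(s), seq = unname(as.character(s)),
                          n_passes = NA_integer_,
                          predicted_accuracy = NA_real_)
  if (!is.null(meta)) {
    m <- readr::read_tsv(meta, comment = "#", show_col_types = FALSE)
    m$n_passes <- as.integer(m$n_passes)
    reads <- dplyr::select(reads, -"n_passes", -"predicted_accuracy")
    reads <- dplyr::left_join(reads, dplyr::rename(m, id = "read_id"),
                              by = "id")
  }
  reads
}
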