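SUBTYPES <- c("SYMMETRIC", "ASYMMETRIC", "NONE")

#' Classification parameters
#'
#' Numeric cutoffs turning the qualitative configuration taxonomy into a
#' decision procedure. None of these are prescribed by the source
#' descriptions of the categories; all are explicit and user-tunable.
#'
#' @param itr_cover_frac Fraction of an ITR interval that must be covered by
#'   aligned segments to call that ITR intact (default 0.9).
#' @param full_genome_frac Fraction of the reference that must be covered to
#'   call a read canonical (default 0.95).
#' @param anchor_tol Distance (nt) within which an SBG arm must reach a
#'   reference terminus (default 50).
#' @param sym_tol Arm-length difference (nt) at or below which an SBG is
#'   SYMMETRIC (default 100).
#' @param min_del Minimum internal reference gap (nt) to call a GDM deletion;
#'   smaller gaps are treated as alignment noise (default 50).
#' @param max_junction_gap Maximum unaligned read bases between the two
#'   segments of an SBG fold or GDM junction (default 50).
#' @return A list of class `classify_params`.
#' @export
classify_params <- function(itr_cover_frac = 0.9, full_genome_frac = 0.95,
                            anchor_tol = 50, sym_tol = 100, min_del = 50,
                            max_junction_gap = 50) {
  stopifnot(itr_cover_frac > 0, itr_cover_frac <= 1,
            full_genome_frac > 0, full_genome_frac <= 1,
            anchor_tol >= 0, sym_tol >= 0, min_del >= 0,
            max_junction_gap >= 0)
  structure(list(itr_cover_frac = itr_cover_frac,
                 full_genome_frac = full_genome_frac,
                 anchor_tol = anchor_tol, sym_tol = sym_tol,
                 min_del = min_del, max_junction_gap = max_junction_gap),
            class = "classify_params")
}

#' ITR coverage flags for a segment chain
#'
#' An ITR is intact when at least `itr_cover_frac` of its reference interval
#' is covered by the union of the chain's segment intervals. Flags are
#' reported in genome frame (left ITR = 5', right ITR = 3' of the
#' plus strand); [classify_read()] normalizes the single retained terminal
#' ITR of an incomplete genome to the 3' flag, since packaging-anchored ends
#' are 3' ends regardless of packaged strand.
#'
#' @param chain Segment tibble for one read.
#' @param ref An `aav_reference`.
#' @param params A [classify_params()].
#' @return Named logical vector `c(itr5, itr3)`.
#' @export
detect_itr_coverage <- function(chain, ref, params = classify_params()) {
  il <- ref_feature(ref, "ITR_LEFT"); ir <- ref_feature(ref, "ITR_RIGHT")
  cov <- function(f) {
    interval_coverage(chain$ref_start, chain$ref_end, f$start, f$end)
  }
  c(itr5 = cov(il) >= params$itr_cover_frac,
    itr3 = cov(ir) >= params$itr_cover_frac)
}

#' Detect a snapback fold point in a segment chain
#'
#' Scans adjacent segment pairs for the fold-back signature: nearly abutting
#' in read coordinates (gap <= `max_junction_gap`), opposite strands, and
#' both reference intervals reaching the SAME reference terminus within
#' `anchor_tol` (both near coordinate 0 = side 5; both near the genome
#' length = side 3). When several pairs qualify, the pair with the longest
#' combined arms wins.
#'
#' @param chain Segment tibble for one read (sorted or not).
#' @param ref_length Reference length in nt.
#' @param params A [classify_params()].
#' @return `NULL`, or a list with `fold_point_read`, `arm_a`, `arm_b`,
#'   `side` (5 or 3), `seg_idx` (row indices of the pair).
#' @export
find_fold_point <- function(chain, ref_length, params = classify_params()) {
  if (nrow(chain) < 2) return(NULL)
  chain <- dplyr::arrange(chain, .data$read_start)
  best <- NULL
  for (i in seq_len(nrow(chain) - 1)) {
    a <- chain[i, ]; b <- chain[i + 1, ]
    gap <- b$read_start - a$read_end
    if (gap < 0 || gap > params$max_junction_gap) next
    if (a$strand == b$strand) next
    near0 <- function(s) s$ref_start <= params$anchor_tol
    nearL <- function(s) (ref_length - s$ref_end) <= params$anchor_tol
    side <- if (near0(a) && near0(b)) 5L else if (nearL(a) && nearL(b)) 3L else NA
    if (is.na(side)) next
    cand <- list(
      fold_point_read = as.integer((a$read_end + b$read_start) %/% 2),
      arm_a = as.integer(a$ref_end - a$ref_start),
      arm_b = as.integer(b$ref_end - b$ref_start),
      side = side, seg_idx = c(i, i + 1)
    )
    if (is.null(best) || cand$arm_a + cand$arm_b > best$arm_a + best$arm_b) {
      best <- cand
    }
  }
  best
}

# are the chain's segments one consistent same-strand walk along the
# reference?  returns list(ok, strand, gaps = tibble(start, end) in plus
# coordinates, covered = union interval list)
collinear_walk <- function(chain) {
  if (nrow(chain) == 0) return(list(ok = FALSE))
  chain <- dplyr::arrange(chain, .data$read_start)
  st <- unique(chain$strand)
  if (length(st) != 1) return(list(ok = FALSE))
  # in read order, plus-strand walks ascend the reference, minus descend
  ord <- if (st == "+") chain else chain[rev(seq_len(nrow(chain))), ]
  if (nrow(ord) > 1) {
    prev_end <- ord$ref_end[-nrow(ord)]
    next_start <- ord$ref_start[-1]
    if (any(next_start < prev_end - 25)) return(list(ok = FALSE))  # backtrack
    gaps <- tibble::tibble(start = pmax(prev_end, ord$ref_start[-nrow(ord)]),
                           end = next_start)
    gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
  } else {
    gaps <- tibble::tibble(start = integer(), end = integer())
  }
  list(ok = TRUE, strand = st, gaps = gaps)
}

empty_call <- function(read_id, read_length) {
  tibble::tibble(
    read_id = read_id, read_length = as.integer(read_length),
    category = NA_character_, subtype = "NONE", strand = NA_character_,
    itr5_intact = NA, itr3_intact = NA,
    fold_point_read = NA_integer_, arm_a = NA_integer_, arm_b = NA_integer_,
    loop_len = NA_integer_, breakpoint = NA_integer_,
    del_start = NA_integer_, del_end = NA_integer_,
    n_segments = 0L, n_gaps = 0L, note = NA_character_,
    annotation = "none"
  )
}

#' Classify one segment chain into a genome configuration
#'
#' The decision tree over a read's segment chain; first match wins:
#' \enumerate{
#'   \item no segments: OTHER;
#'   \item a single same-strand collinear walk with reference gaps below
#'     `min_del`, covering at least `full_genome_frac` of the genome
#'     including both ITRs: CANONICAL;
#'   \item a fold point: SBG_5 / SBG_3 by fold side, subtype by `sym_tol`;
#'   \item a collinear walk (gaps < `min_del`) with exactly one terminal ITR
#'     intact: ICG, breakpoint at the interior end of the covered interval
#'     (plus-strand coordinates);
#'   \item a collinear walk with both ITRs intact and a largest internal
#'     reference gap of at least `min_del`: GDM, deletion = that gap;
#'   \item otherwise OTHER.
#' }
#' ICG calls report `itr3_intact = TRUE, itr5_intact = FALSE` for the
#' retained terminal ITR: packaging anchors at a 3' ITR, so the retained
#' terminus is the molecule's 3' end whichever genome terminus it maps to.
#'
#' @param chain Segment tibble for one read.
#' @param ref An `aav_reference`.
#' @param params A [classify_params()].
#' @param read_id,read_length Used when the chain is empty.
#' @return A one-row configuration-call tibble.
#' @export
classify_read <- function(chain, ref, params = classify_params(),
                          read_id = NULL, read_length = NULL) {
  if (is.null(read_id)) read_id <- chain$read_id[1]
  if (is.null(read_length)) read_length <- chain$read_length[1]
  call <- empty_call(read_id, read_length)
  call$n_segments <- nrow(chain)
  if (nrow(chain) == 0) {
    call$category <- "OTHER"
    return(call)
  }
  chain <- dplyr::arrange(chain, .data$read_start)
  L <- ref$length
  itr <- detect_itr_coverage(chain, ref, params)
  walk <- collinear_walk(chain)
  genome_cov <- interval_coverage(chain$ref_start, chain$ref_end, 0, L)
  fold <- find_fold_point(chain, L, params)

  if (walk$ok && (nrow(walk$gaps) == 0 ||
                  max(walk$gaps$end - walk$gaps$start) < params$min_del) &&
      genome_cov >= params$full_genome_frac && itr["itr5"] && itr["itr3"]) {
    call$category <- "CANONICAL"
    call$strand <- walk$strand
    call$itr5_intact <- TRUE; call$itr3_intact <- TRUE
  } else if (!is.null(fold)) {
    call$category <- if (fold$side == 5L) "SBG_5" else "SBG_3"
    call$subtype <- if (abs(fold$arm_a - fold$arm_b) <= params$sym_tol) {
      "SYMMETRIC"
    } else "ASYMMETRIC"
    # the covalent orientation of a fold-back molecule is indistinguishable
    # from its arm-swapped reverse complement, so no strand is reported
    call$strand <- NA_character_
    call$fold_point_read <- fold$fold_point_read
    call$arm_a <- fold$arm_a; call$arm_b <- fold$arm_b
    call$loop_len <- abs(fold$arm_a - fold$arm_b)
    call$itr5_intact <- unname(itr["itr5"]); call$itr3_intact <- unname(itr["itr3"])
    if (walk$ok && nrow(walk$gaps) > 0 &&
        max(walk$gaps$end - walk$gaps$start) >= params$min_del) {
      call$note <- "fold_plus_internal_deletion"
    }
  } else if (walk$ok && (nrow(walk$gaps) == 0 ||
                         max(walk$gaps$end - walk$gaps$start) < params$min_del) &&
             xor(itr["itr5"], itr["itr3"])) {
    call$category <- "ICG"
    call$strand <- walk$strand
    # retained terminal ITR is by definition the molecule's 3' end
    call$itr5_intact <- FALSE; call$itr3_intact <- TRUE
    a <- min(chain$ref_start); b <- max(chain$ref_end)
    call$breakpoint <- if (itr["itr3"]) as.integer(a) else as.integer(b)
  } else if (walk$ok && itr["itr5"] && itr["itr3"] && nrow(walk$gaps) > 0 &&
             max(walk$gaps$end - walk$gaps$start) >= params$min_del) {
    big <- walk$gaps[walk$gaps$end - walk$gaps$start >= params$min_del, ]
    widest <- big[which.max(big$end - big$start), ]
    call$category <- "GDM"
    call$strand <- walk$strand
    call$itr5_intact <- TRUE; call$itr3_intact <- TRUE
    call$del_start <- as.integer(widest$start)
    call$del_end <- as.integer(widest$end)
    call$n_gaps <- nrow(big)
  } else {
    call$category <- "OTHER"
  }
  call$annotation <- annotate_regulatory_potential(call, ref, chain)
  call
}

#' Annotate the regulatory potential of a configuration call
#'
#' Pure rule lookup on the dimer geometry of snapback genomes: a 5'-SBG
#' whose covered interval contains the P5 promoter forms a tail-to-tail
#' dimer whose read-through transcripts can fold into dsRNA (predicted Rep78
#' down-regulation); a 3'-SBG whose covered interval contains P40 forms a
#' head-to-head dimer with two P40 promoters sharing a central enhancer
#' neighbourhood (predicted cap up-regulation). Everything else maps to
#' `"none"`. A promoter counts as contained when at least half its interval
#' is covered.
#'
#' @param call A one-row configuration-call tibble.
#' @param ref An `aav_reference`.
#' @param chain The segment chain the call came from (for covered
#'   intervals); optional for non-SBG calls.
#' @return A single annotation string.
#' @export
annotate_regulatory_potential <- function(call, ref, chain = NULL) {
  if (!call$category %in% c("SBG_5", "SBG_3") || is.null(chain) ||
      nrow(chain) == 0) {
    return("none")
  }
  covered <- function(role) {
    f <- ref_feature(ref, role)
    interval_coverage(chain$ref_start, chain$ref_end, f$start, f$end) >= 0.5
  }
  if (call$category == "SBG_5" && covered("P5")) {
    "tail-to-tail-dimer; dsRNA-capable; predicted Rep78 down-regulation"
  } else if (call$category == "SBG_3" && covered("P40")) {
    "head-to-head-P40; double-enhancer; predicted cap up-regulation"
  } else {
    "none"
  }
}

#' Classify a read population
#'
#' Runs [segment_read()] and [classify_read()] over every read. Per-read
#' failures are caught and reported as OTHER with the error in the `note`
#' column.
#'
#' @param reads A reads tibble (`id`, `seq`), normally QC-passed.
#' @param ref An `aav_reference`.
#' @param align An [align_params()].
#' @param params A [classify_params()].
#' @return A configuration-call tibble, one row per read, in input order.
#' @examples
#' ref <- build_reference()
#' reads <- simulate_population(ref, sim_config(n_reads = 12, seed = 3))
#' calls <- classify_reads(reads, ref)
#' dplyr::count(calls, category)
#' @export
classify_reads <- function(reads, ref, align = align_params(),
                           params = classify_params()) {
  purrr::map2_dfr(reads$seq, reads$id, function(s, id) {
    tryCatch({
      chain <- segment_read(s, ref, align, read_id = id)
      classify_read(chain, ref, params, read_id = id,
                    read_length = nchar(s))
    }, error = function(e) {
      call <- empty_call(id, nchar(s))
      call$category <- "OTHER"
      call$note <- paste0("error: ", conditionMessage(e))
      call
    })
  })
}

#' Classify precomputed segment chains
#'
#' Variant of [classify_reads()] that reuses an existing segment table
#' (keyed by `read_id`) instead of realigning.
#'
#' @param chains Segment tibble from [segment_reads()].
#' @param reads The reads tibble the chains came from (for read ids/lengths
#'   of reads with empty chains).
#' @param ref An `aav_reference`.
#' @param params A [classify_params()].
#' @return A configuration-call tibble, one row per read.
#' @export
classify_chains <- function(chains, reads, ref, params = classify_params()) {
  split_chains <- split(chains, chains$read_id)
  purrr::map2_dfr(reads$id, nchar(reads$seq), function(id, len) {
    ch <- split_chains[[id]]
    if (is.null(ch)) ch <- chains[0, ]
    classify_read(ch, ref, params, read_id = id, read_length = len)
  })
}

#' Write a configuration-call table
#'
#' @param calls Call tibble from [classify_reads()].
#' @param path Output path.
#' @param seed Seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, seed = NULL) {
  writeLines(provenance_header(seed), path)
  readr::write_tsv(calls, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
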