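#' Alignment parameters
#'
#' Scoring and acceptance thresholds for the local aligner and the iterative
#' flank-realignment loop. The default scoring (match 2, mismatch -4, gap
#' open -4, gap extend -2) is megablast-like; a gap of length g costs
#' `gap_open + g * gap_extend`.
#'
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @param min_segment_len Minimum read-span (nt) for a segment to qualify.
#' @param min_identity Minimum identity (matches / alignment columns).
#' @param max_depth Flank-recursion depth limit.
#' @param kmer Seed k-mer size for the banded heuristic.
#' @param band_pad Band half-width padding (nt) around seeded diagonals.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -4, gap_open = -4,
                         gap_extend = -2, min_segment_len = 50,
                         min_identity = 0.85, max_depth = 6, kmer = 13,
                         band_pad = 32) {
  if (min_segment_len < 20) stop("min_segment_len must be >= 20")
  if (min_identity <= 0.5 || min_identity > 1) {
    stop("min_identity must be in (0.5, 1]")
  }
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_segment_len = as.integer(min_segment_len),
                 min_identity = min_identity,
                 max_depth = as.integer(max_depth), kmer = as.integer(kmer),
                 band_pad = as.integer(band_pad)),
            class = "align_params")
}

ref_seq_of <- function(ref) {
  if (inherits(ref, "aav_reference")) ref$seq else normalize_dna(ref)
}

# segments are split out of one alignment at any gap run >= split_gap, so a
# long internal deletion becomes two collinear segments (per-HSP behaviour)
SPLIT_GAP <- 30L

# best local hit over both strands with its blocks; NULL if nothing found.
# the C++ engine handles both strands, coordinate mapping, and the total
# tie-break order (score desc, span desc, ref_start asc, plus before minus)
best_local_hit <- function(query, ref_seq, params, force_full = FALSE) {
  # a reportable hit must reach roughly this score; seedless queries whose
  # score-only pass stays below it skip the traceback DP entirely
  floor_score <- if (force_full) 0L else max(0L, as.integer(floor(
    0.7 * params$min_segment_len *
      (params$min_identity * params$match +
         (1 - params$min_identity) * params$mismatch))))
  h <- cpp_local_align(query, ref_seq, params$match, params$mismatch,
                       params$gap_open, params$gap_extend, params$kmer,
                       params$band_pad, SPLIT_GAP, force_full, floor_score)
  if (!h$found) return(NULL)
  h$identity <- sum(h$block_matches) / max(1L, sum(h$block_columns))
  h
}

#' Best local alignment of a query against the reference
#'
#' Affine-gap local alignment over both strands (the minus strand aligns the
#' reverse complement of the query, with read coordinates mapped back).
#' Ties between strands break to highest score, then longest aligned span,
#' then smallest `ref_start`, then plus before minus — a total order, so the
#' result is deterministic. Returns `NULL` when the best hit is shorter than
#' `min_segment_len` on the read or below `min_identity`.
#'
#' @param query A DNA string (non-ACGT characters are treated as N and never
#'   match).
#' @param ref An `aav_reference` or a plain DNA string.
#' @param params An [align_params()].
#' @param force_full Bypass the seeding heuristic and run the full dynamic
#'   program (used by tests).
#' @return One-row tibble `read_start read_end ref_start ref_end strand
#'   identity score` (0-based half-open), or `NULL`.
#' @export
local_align <- function(query, ref, params = align_params(),
                        force_full = FALSE) {
  q <- normalize_dna(query)
  if (nchar(q) == 0) return(NULL)
  h <- best_local_hit(q, ref_seq_of(ref), params, force_full)
  if (is.null(h)) return(NULL)
  if ((h$read_end - h$read_start) < params$min_segment_len ||
      h$identity < params$min_identity) {
    return(NULL)
  }
  tibble::tibble(read_start = as.integer(h$read_start),
                 read_end = as.integer(h$read_end),
                 ref_start = as.integer(h$ref_start),
                 ref_end = as.integer(h$ref_end),
                 strand = h$strand, identity = h$identity,
                 score = as.integer(h$score))
}

#' Segment a read by iterative flank realignment
#'
#' The categorization engine's inner loop: align the whole read locally to
#' the reference; when a qualifying segment is found, record it and realign
#' the unmatched left and right flanks independently, recursing until no
#' qualifying hit remains, a flank is shorter than `min_segment_len`, or
#' `max_depth` is reached. Segments are disjoint in read coordinates by
#' construction.
#'
#' @param seq The read sequence.
#' @param ref An `aav_reference` or DNA string.
#' @param params An [align_params()].
#' @param read_id Identifier copied into the output.
#' @param force_full Bypass the seeding heuristic (tests).
#' @return A segment tibble (`read_id read_length read_start read_end
#'   ref_start ref_end strand identity score`), sorted by `read_start`;
#'   zero rows when nothing aligns.
#' @export
segment_read <- function(seq, ref, params = align_params(),
                         read_id = NA_character_, force_full = FALSE) {
  q <- normalize_dna(seq)
  n <- nchar(q)
  rs <- ref_seq_of(ref)
  acc <- vector("list", 32)
  n_acc <- 0L
  recurse <- function(lo, hi, depth) {
    if (hi - lo < params$min_segment_len || depth > params$max_depth) {
      return(invisible())
    }
    h <- best_local_hit(substr(q, lo + 1, hi), rs, params, force_full)
    if (is.null(h) ||
        (h$read_end - h$read_start) < params$min_segment_len ||
        h$identity < params$min_identity) {
      return(invisible())
    }
    keep <- (h$block_read_end - h$block_read_start) >= 20L
    n_acc <<- n_acc + 1L
    acc[[n_acc]] <<- list(
      read_start = h$block_read_start[keep] + lo,
      read_end = h$block_read_end[keep] + lo,
      ref_start = h$block_ref_start[keep],
      ref_end = h$block_ref_end[keep],
      strand = rep(h$strand, sum(keep)),
      identity = h$block_matches[keep] / pmax(1L, h$block_columns[keep]),
      score = h$block_score[keep])
    recurse(lo, lo + h$read_start, depth + 1)
    recurse(lo + h$read_end, hi, depth + 1)
    invisible()
  }
  recurse(0L, n, 1L)
  acc <- acc[seq_len(n_acc)]
  col <- function(f, empty) {
    if (n_acc == 0) empty else unlist(lapply(acc, `[[`, f), use.names = FALSE)
  }
  segs <- tibble::tibble(
    read_id = read_id, read_length = n,
    read_start = as.integer(col("read_start", integer())),
    read_end = as.integer(col("read_end", integer())),
    ref_start = as.integer(col("ref_start", integer())),
    ref_end = as.integer(col("ref_end", integer())),
    strand = col("strand", character()),
    identity = col("identity", numeric()),
    score = as.integer(col("score", integer())))
  if (nrow(segs) == 0) {
    segs$read_id <- character(); segs$read_length <- integer()
    return(segs)
  }
  segs[order(segs$read_start), , drop = FALSE]
}

#' Segment every read in a population
#'
#' @param reads A reads tibble (`id`, `seq`).
#' @param ref An `aav_reference`.
#' @param params An [align_params()].
#' @return A segment tibble over all reads (one row per segment).
#' @export
segment_reads <- function(reads, ref, params = align_params()) {
  purrr::map2_dfr(reads$seq, reads$id,
                  function(s, id) segment_read(s, ref, params, read_id = id))
}

#' Read intervals not covered by any segment
#'
#' @param chain Segment tibble for one read.
#' @param read_length Read length (taken from the chain when present).
#' @return Tibble of half-open uncovered read intervals.
#' @export
chain_uncovered <- function(chain, read_length = NULL) {
  if (is.null(read_length)) read_length <- chain$read_length[1]
  pos <- 0L
  out <- list()
  if (nrow(chain) > 0) {
    chain <- dplyr::arrange(chain, .data$read_start)
    for (i in seq_len(nrow(chain))) {
      if (chain$read_start[i] > pos) {
        out[[length(out) + 1]] <- c(pos, chain$read_start[i])
      }
      pos <- max(pos, chain$read_end[i])
    }
  }
  if (pos < read_length) out[[length(out) + 1]] <- c(pos, read_length)
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(start = m[, 1], end = m[, 2])
}

#' Write a segment-chain table
#'
#' Tab-separated with `#` provenance header lines.
#'
#' @param chains Segment tibble from [segment_reads()].
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_chains <- function(chains, path, seed = NULL) {
  writeLines(provenance_header(seed), path)
  readr::write_tsv(chains, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
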