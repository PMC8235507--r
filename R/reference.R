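#' Synthesize a palindromic ITR sequence
#'
#' Builds a GC-rich perfect palindrome standing in for an AAV inverted
#' terminal repeat: the first half is drawn at a fixed GC composition and the
#' second half is its reverse complement, so `revcomp(s) == s` exactly.
#'
#' @param length Even ITR length in nt (>= 20). Default 144.
#' @param gc Target GC fraction of the ITR (>= 0.6 guaranteed). Default 0.7.
#' @param seed Optional integer seed; when given the draw is made under a
#'   temporary RNG state.
#' @return A single DNA string.
#' @examples
#' itr <- make_itr(144, seed = 1)
#' identical(revcomp(itr), itr)
#' @export
make_itr <- function(length = 144, gc = 0.7, seed = NULL) {
  if (length %% 2 != 0 || length < 20) {
    stop("ITR length must be an even integer >= 20, got ", length)
  }
  if (gc < 0.6 || gc > 1) stop("ITR gc must be in [0.6, 1]")
  half <- length / 2L
  n_gc <- ceiling(gc * half)
  with_seed_if(seed, {
    comp <- c(sample(c("G", "C"), n_gc, replace = TRUE),
              sample(c("A", "T"), half - n_gc, replace = TRUE))
    h <- paste(sample(comp), collapse = "")
    paste0(h, revcomp(h))
  })
}

#' Reference genome layout configuration
#'
#' Parameters controlling [build_reference()]. Promoter and ORF positions are
#' fractions of the total genome length; the defaults place P5 and the rep
#' ORF in the left moiety and P40 and the cap ORF in the right moiety, the
#' geometry on which 5'- vs 3'-snapback annotation rests.
#'
#' @param length Total genome length in nt (default 4700).
#' @param itr_length Even ITR length in nt (default 144).
#' @param p5,p19,p40 Promoter start positions as fractions of `length`.
#' @param promoter_width Promoter interval width in nt (default 50).
#' @param rep_orf,cap_orf Two-element fraction vectors `c(start, end)`.
#' @param seed Integer seed making the built sequence reproducible.
#' @return A list of class `ref_config`.
#' @export
ref_config <- function(length = 4700, itr_length = 144,
                       p5 = 0.055, p19 = 0.19, p40 = 0.38,
                       promoter_width = 50,
                       rep_orf = c(0.06, 0.48), cap_orf = c(0.45, 0.95),
                       seed = 1) {
  structure(
    list(length = as.integer(length), itr_length = as.integer(itr_length),
         p5 = p5, p19 = p19, p40 = p40,
         promoter_width = as.integer(promoter_width),
         rep_orf = rep_orf, cap_orf = cap_orf, seed = seed),
    class = "ref_config"
  )
}

new_aav_reference <- function(seq, features) {
  structure(
    list(seq = seq, length = nchar(seq), features = features),
    class = "aav_reference"
  )
}

#' @export
print.aav_reference <- function(x, ...) {
  cat("<aav_reference> ", x$length, " nt, ", nrow(x$features), " features\n",
      sep = "")
  print(x$features)
  invisible(x)
}

ref_feature <- function(ref, role) {
  f <- ref$features[ref$features$role == role, , drop = FALSE]
  if (nrow(f) != 1) stop("reference has no unique feature of role ", role)
  f
}

validate_reference <- function(ref) {
  stopifnot(inherits(ref, "aav_reference"))
  if (ref$length != nchar(ref$seq)) stop("length field disagrees with seq")
  f <- ref$features
  need <- c("role", "start", "end", "strand")
  if (!all(need %in% names(f))) {
    stop("features must have columns: ", paste(need, collapse = " "))
  }
  if (anyDuplicated(f$role)) stop("feature roles must be unique")
  roles <- c("ITR_LEFT", "ITR_RIGHT", "P5", "P19", "P40", "REP_ORF", "CAP_ORF")
  miss <- setdiff(c("ITR_LEFT", "ITR_RIGHT"), f$role)
  if (length(miss)) stop("missing required feature role(s): ",
                         paste(miss, collapse = ", "))
  if (!all(f$role %in% roles)) {
    stop("unknown feature role(s): ",
         paste(setdiff(f$role, roles), collapse = ", "))
  }
  if (any(f$start >= f$end)) stop("feature start must be < end")
  if (any(f$start < 0) || any(f$end > ref$length)) {
    bad <- f[f$start < 0 | f$end > ref$length, ]
    stop("feature interval out of range: ", bad$role[1], " [", bad$start[1],
         ", ", bad$end[1], ") vs genome length ", ref$length)
  }
  il <- ref_feature(ref, "ITR_LEFT"); ir <- ref_feature(ref, "ITR_RIGHT")
  if (il$start != 0) stop("ITR_LEFT must start at coordinate 0")
  if (ir$end != ref$length) stop("ITR_RIGHT must end at the genome length")
  itr_len <- il$end - il$start
  if (ref$length < 2 * itr_len + 1000) {
    stop("genome too short for its ITRs (need >= 2 x ITR + 1000 nt)")
  }
  proms <- f[f$role %in% c("P5", "P19", "P40"), ]
  if (nrow(proms) == 3) {
    p <- proms$start[match(c("P5", "P19", "P40"), proms$role)]
    if (!(p[1] < p[2] && p[2] < p[3])) stop("promoters must satisfy P5 < P19 < P40")
  }
  invisible(ref)
}

#' Build a synthetic AAV reference genome
#'
#' Constructs a reference with perfect-palindrome ITRs at both termini (the
#' right ITR is the reverse complement of the left one, hence identical for a
#' perfect palindrome), a uniformly random interior, and the promoter/ORF
#' layout from the configuration. Deterministic for a fixed config seed.
#'
#' @param config A [ref_config()].
#' @return An `aav_reference` object: fields `seq` (character), `length`,
#'   and `features` (tibble with `role start end strand`, 0-based half-open).
#' @examples
#' ref <- build_reference(ref_config(seed = 1))
#' ref$length
#' @export
build_reference <- function(config = ref_config()) {
  stopifnot(inherits(config, "ref_config"))
  L <- config$length; itr <- config$itr_length
  pw <- config$promoter_width
  starts <- floor(c(config$p5, config$p19, config$p40) * L)
  if (any(starts < itr) || any(starts + pw > L - itr)) {
    stop("promoter layout overlaps an ITR; adjust fractions or ITR length")
  }
  orf <- function(fr) pmin(pmax(floor(fr * L), itr), L - itr)
  rep_iv <- orf(config$rep_orf); cap_iv <- orf(config$cap_orf)
  seq <- with_seed_if(config$seed, {
    left <- make_itr(itr, seed = NULL)
    interior <- random_dna(L - 2L * itr)
    paste0(left, interior, revcomp(left))
  })
  features <- tibble::tibble(
    role = c("ITR_LEFT", "ITR_RIGHT", "P5", "P19", "P40", "REP_ORF", "CAP_ORF"),
    start = as.integer(c(0, L - itr, starts, rep_iv[1], cap_iv[1])),
    end = as.integer(c(itr, L, starts + pw, rep_iv[2], cap_iv[2])),
    strand = "+"
  )
  validate_reference(new_aav_reference(seq, features))
}

#' Write a reference genome to FASTA + feature TSV
#'
#' @param ref An `aav_reference`.
#' @param fasta,features Output paths.
#' @return The input, invisibly.
#' @export
write_reference <- function(ref, fasta, features) {
  validate_reference(ref)
  s <- Biostrings::DNAStringSet(ref$seq)
  names(s) <- "AAV_reference"
  Biostrings::writeXStringSet(s, fasta)
  readr::write_tsv(ref$features, features)
  invisible(ref)
}

#' Load a reference genome from FASTA + feature TSV
#'
#' The FASTA must contain a single record; the feature table needs columns
#' `role start end strand`. All structural invariants are validated.
#'
#' @param fasta Path to a single-record FASTA.
#' @param features Path to the feature TSV.
#' @return An `aav_reference`.
#' @export
read_reference <- function(fasta, features) {
  s <- Biostrings::readDNAStringSet(fasta)
  if (length(s) != 1) {
    stop("reference FASTA must contain exactly one record, found ", length(s))
  }
  f <- readr::read_tsv(features, show_col_types = FALSE, comment = "#")
  f$start <- as.integer(f$start); f$end <- as.integer(f$end)
  validate_reference(new_aav_reference(as.character(s[[1]]), tibble::as_tibble(f)))
}

# interior (non-ITR) interval of the genome, 0-based half-open
ref_interior <- function(ref) {
  c(ref_feature(ref, "ITR_LEFT")$end, ref_feature(ref, "ITR_RIGHT")$start)
}
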