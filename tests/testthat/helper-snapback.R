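# shared fixtures and independent oracles for the test suite; everything is
# generated in code under fixed seeds

.shared <- new.env(parent = emptyenv())

# default 4700 nt reference, built once
test_ref <- function() {
  if (is.null(.shared$ref)) .shared$ref <- build_reference(ref_config(seed = 101))
  .shared$ref
}

# memoised populations (classification is the expensive step)
memo <- function(key, expr) {
  if (is.null(.shared[[key]])) .shared[[key]] <- force(expr)
  .shared[[key]]
}

# error-free quota population of n reads + its calls
errorfree_population <- function(n = 1000, seed = 201) {
  memo(paste0("ef", n, "_", seed), {
    ref <- test_ref()
    reads <- simulate_population(ref, sim_config(
      n_reads = n, sub_rate = 0, ins_rate = 0, del_rate = 0,
      qc_fail_frac = 0, seed = seed))
    list(reads = reads, calls = classify_reads(reads, ref))
  })
}

# default-error quota population of n reads + its calls
noisy_population <- function(n = 1000, seed = 301) {
  memo(paste0("noisy", n, "_", seed), {
    ref <- test_ref()
    reads <- simulate_population(ref, sim_config(
      n_reads = n, qc_fail_frac = 0, seed = seed))
    list(reads = reads, calls = classify_reads(reads, ref))
  })
}

# --- oracle 1: exhaustive exact-match decomposition ------------------------
# maximal exact substring matches between a read and a (small) reference,
# enumerated per diagonal; independent of the package's aligner.

# all maximal exact matches of r against t on one orientation, as a data
# frame of qs/qe/ts/te (0-based half-open) in the given frame
exact_matches_frame <- function(r, t) {
  rb <- strsplit(r, "")[[1]]; tb <- strsplit(t, "")[[1]]
  n <- length(rb); m <- length(tb)
  out <- list()
  for (d in (-(n - 1)):(m - 1)) {
    i <- max(1, 1 - d); j <- i + d          # 1-based alignment start
    len <- min(n - i, m - j) + 1
    if (len < 1) next
    eq <- rb[i:(i + len - 1)] == tb[j:(j + len - 1)]
    rl <- rle(eq)
    pos <- cumsum(c(0, rl$lengths[-length(rl$lengths)]))
    for (k in seq_along(rl$lengths)) {
      if (rl$values[k]) {
        qs <- i - 1 + pos[k]
        out[[length(out) + 1]] <-
          c(qs = qs, qe = qs + rl$lengths[k], ts = j - 1 + pos[k],
            te = j - 1 + pos[k] + rl$lengths[k])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(qs = integer(), qe = integer(), ts = integer(),
                      te = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# best exact match over both strands with the aligner's tie-break order:
# longest, then smallest ref start, then plus before minus
oracle_best_exact <- function(r, t, min_len) {
  n <- nchar(r)
  plus <- exact_matches_frame(r, t)
  plus$strand <- rep("+", nrow(plus))
  minus <- exact_matches_frame(revcomp(r), t)
  if (nrow(minus) > 0) {
    qs <- n - minus$qe; minus$qe <- n - minus$qs; minus$qs <- qs
  }
  minus$strand <- rep("-", nrow(minus))
  all <- rbind(plus, minus)
  all <- all[all$qe - all$qs >= min_len, , drop = FALSE]
  if (nrow(all) == 0) return(NULL)
  all <- all[order(-(all$qe - all$qs), all$ts, all$strand, all$qs), ]
  all[1, ]
}

# recursive exact-match decomposition mirroring the flank-realignment loop
oracle_decompose <- function(r, t, min_len = 30, max_depth = 6) {
  recurse <- function(lo, hi, depth) {
    if (hi - lo < min_len || depth > max_depth) return(NULL)
    sub <- substr(r, lo + 1, hi)
    b <- oracle_best_exact(sub, t, min_len)
    if (is.null(b)) return(NULL)
    b$qs <- b$qs + lo; b$qe <- b$qe + lo
    rbind(recurse(lo, b$qs, depth + 1), b, recurse(b$qe, hi, depth + 1))
  }
  res <- recurse(0L, nchar(r), 1L)
  if (is.null(res)) {
    return(data.frame(qs = integer(), qe = integer(), ts = integer(),
                      te = integer(), strand = character()))
  }
  res[order(res$qs), ]
}

# --- oracle 2: reference local-alignment score via Biostrings --------------
biostrings_local_score <- function(query, target, match = 2, mismatch = -4,
                                   gap_open = 4, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(target),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE)
}

# random point mutations at rate p (substitutions only)
mutate_subs <- function(s, p) {
  b <- strsplit(s, "")[[1]]
  i <- which(stats::runif(length(b)) < p)
  if (length(i)) {
    b[i] <- vapply(b[i], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  }
  paste(b, collapse = "")
}
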