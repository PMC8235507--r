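BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over character DNA sequences (IUPAC letters
#' supported via Biostrings).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector of G+C fractions.
#' @export
gc_fraction <- function(x) {
  s <- Biostrings::DNAStringSet(x)
  f <- Biostrings::letterFrequency(s, c("G", "C"))
  as.numeric(rowSums(f) / Biostrings::width(s))
}

# uniform random DNA of length n (scalar)
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# uppercase and map every non-ACGT character to N
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

# coverage of the interval [lo, hi) by a set of [start, end) intervals,
# returned as a fraction of hi - lo
interval_coverage <- function(start, end, lo, hi) {
  if (length(start) == 0 || hi <= lo) return(0)
  s <- pmax(start, lo)
  e <- pmin(end, hi)
  keep <- s < e
  if (!any(keep)) return(0)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0; cs <- s[1]; ce <- e[1]
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] > ce) { tot <- tot + (ce - cs); cs <- s[i]; ce <- e[i] }
      else ce <- max(ce, e[i])
    }
  }
  tot <- tot + (ce - cs)
  tot / (hi - lo)
}

# run code under a temporary RNG seed when one is given
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# provenance header lines for TSV/JSON artifacts
provenance_header <- function(seed = NULL, extra = character()) {
  c(
    paste0("# snapback v", as.character(utils::packageVersion("snapback"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    extra
  )
}
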