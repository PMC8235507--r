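#' Read-level QC parameters
#'
#' Thresholds emulating consensus-read filtering: a read is kept when it has
#' at least `min_passes` polymerase passes AND a predicted accuracy of at
#' least `min_predicted_accuracy` (both inclusive, "min" semantics).
#'
#' @param min_passes Minimum pass count (default 3).
#' @param min_predicted_accuracy Minimum predicted accuracy (default 0.99).
#' @param length_bins Optional numeric breaks for [bin_reads_by_length()].
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_passes = 3, min_predicted_accuracy = 0.99,
                      length_bins = NULL) {
  if (min_passes < 1) stop("min_passes must be >= 1")
  if (min_predicted_accuracy < 0 || min_predicted_accuracy > 1) {
    stop("min_predicted_accuracy must be in [0, 1]")
  }
  structure(list(min_passes = min_passes,
                 min_predicted_accuracy = min_predicted_accuracy,
                 length_bins = length_bins),
            class = "qc_params")
}

#' Filter reads on consensus-quality metadata
#'
#' Keeps reads with `n_passes >= min_passes` and
#' `predicted_accuracy >= min_predicted_accuracy` (inclusive thresholds),
#' preserving input order. Kept/dropped counts are attached as the
#' `qc_counts` attribute and reported via `message()`.
#'
#' @param reads A reads tibble with `n_passes` and `predicted_accuracy`.
#' @param params A [qc_params()].
#' @param on_missing `"drop"` (default): reads with missing metadata are
#'   dropped with a warning; `"error"`: they abort.
#' @param quiet Suppress the count message.
#' @return The filtered reads tibble.
#' @export
qc_filter <- function(reads, params = qc_params(),
                      on_missing = c("drop", "error"), quiet = FALSE) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(params, "qc_params"))
  if (!all(c("n_passes", "predicted_accuracy") %in% names(reads))) {
    stop("reads must carry n_passes and predicted_accuracy columns")
  }
  miss <- is.na(reads$n_passes) | is.na(reads$predicted_accuracy)
  if (any(miss)) {
    if (on_missing == "error") {
      stop(sum(miss), " read(s) lack QC metadata")
    }
    warning(sum(miss), " read(s) lack QC metadata and were dropped")
  }
  keep <- !miss &
    reads$n_passes >= params$min_passes &
    reads$predicted_accuracy >= params$min_predicted_accuracy
  out <- reads[keep, , drop = FALSE]
  counts <- c(input = nrow(reads), kept = sum(keep),
              dropped = sum(!keep))
  if (!quiet) {
    message("qc_filter: kept ", counts["kept"], "/", counts["input"],
            " reads (dropped ", counts["dropped"], ")")
  }
  attr(out, "qc_counts") <- counts
  out
}

#' Stratify reads into length bins
#'
#' Assigns each read to a half-open length interval; reads outside every bin
#' land in `"unbinned"`. Bin counts always partition the input.
#'
#' @param reads A reads tibble with a `seq` column.
#' @param breaks Sorted numeric vector of bin boundaries; consecutive pairs
#'   define half-open intervals `[breaks[i], breaks[i+1])`. Default: 500 nt
#'   steps from 0 to 5000.
#' @return The reads tibble with a `length_bin` factor column.
#' @export
bin_reads_by_length <- function(reads, breaks = seq(0, 5000, by = 500)) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing")
  }
  len <- nchar(reads$seq)
  idx <- findInterval(len, breaks)  # i: breaks[i] <= len < breaks[i+1]
  labels <- sprintf("[%g,%g)", utils::head(breaks, -1), breaks[-1])
  bin <- ifelse(idx >= 1 & idx < length(breaks), labels[idx], "unbinned")
  reads$length_bin <- factor(bin, levels = c(labels, "unbinned"))
  reads
}
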