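#' Chi-square test of breakpoint uniformity
#'
#' The formal version of the "no hot spots" claim for incomplete genomes:
#' observed breakpoint counts over equal-width bins spanning the non-ITR
#' interior are compared with the uniform expectation by a Pearson
#' chi-square test. Bins whose expected count falls below 5 are merged with
#' a neighbour (standard validity rule); `df = final bins - 1`.
#'
#' @param breakpoints Numeric vector of breakpoint reference coordinates, or
#'   a configuration-call tibble (its ICG rows' `breakpoint` column is
#'   used).
#' @param ref An `aav_reference` supplying the interior interval, or a
#'   two-element numeric `c(lo, hi)`.
#' @param n_bins Initial number of equal-width bins (default 20).
#' @return An object of class `htest` with `statistic` (X-squared),
#'   `parameter` (df), `p.value`, and `observed`/`expected` counts.
#' @examples
#' ref <- build_reference()
#' bp <- runif(500, 144, 4556)
#' breakpoint_uniformity_test(bp, ref)
#' @export
breakpoint_uniformity_test <- function(breakpoints, ref, n_bins = 20) {
  if (is.data.frame(breakpoints)) {
    breakpoints <- breakpoints$breakpoint[breakpoints$category == "ICG"]
  }
  rng <- if (inherits(ref, "aav_reference")) ref_interior(ref) else ref
  breakpoints <- breakpoints[!is.na(breakpoints) &
                               breakpoints >= rng[1] & breakpoints < rng[2]]
  n <- length(breakpoints)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  obs <- as.vector(table(cut(breakpoints, breaks, right = FALSE,
                             include.lowest = TRUE)))
  exp_ <- rep(n / n_bins, n_bins)
  # merge under-filled bins with their right neighbour (left for the last)
  while (length(obs) > 2 && min(exp_) < 5) {
    i <- which.min(exp_)
    j <- if (i < length(obs)) i + 1 else i - 1
    obs[j] <- obs[j] + obs[i]; exp_[j] <- exp_[j] + exp_[i]
    obs <- obs[-i]; exp_ <- exp_[-i]
  }
  if (length(obs) < 2 || min(exp_) < 5) {
    stop("too few breakpoints for a uniformity test (need >= 5 expected per ",
         "bin in at least 2 bins)")
  }
  stat <- sum((obs - exp_)^2 / exp_)
  df <- length(obs) - 1L
  structure(
    list(statistic = c(`X-squared` = stat), parameter = c(df = df),
         p.value = stats::pchisq(stat, df, lower.tail = FALSE),
         method = "Chi-square test of breakpoint uniformity",
         data.name = paste(n, "breakpoints in", length(obs), "bins"),
         observed = obs, expected = exp_),
    class = "htest"
  )
}

#' Histogram of snapback arm asymmetry
#'
#' Counts of the single-stranded loop length `|arm_a - arm_b|` over SBG
#' calls, binned at `bin_width`.
#'
#' @param calls A configuration-call tibble (non-SBG rows are ignored).
#' @param bin_width Bin width in nt (default 100).
#' @return Tibble `loop_lo loop_hi count`; counts total the SBG count.
#' @export
arm_symmetry_histogram <- function(calls, bin_width = 100) {
  loops <- calls$loop_len[calls$category %in% c("SBG_5", "SBG_3") &
                            !is.na(calls$loop_len)]
  if (length(loops) == 0) {
    return(tibble::tibble(loop_lo = integer(), loop_hi = integer(),
                          count = integer()))
  }
  idx <- loops %/% bin_width
  tab <- table(idx)
  tibble::tibble(
    loop_lo = as.integer(names(tab)) * as.integer(bin_width),
    loop_hi = (as.integer(names(tab)) + 1L) * as.integer(bin_width),
    count = as.integer(tab)
  )
}

#' Summarize a classified virion population
#'
#' Aggregates configuration calls into population-level quantities: per-
#' category counts and fractions, read-length quartiles per category, the
#' ICG/SBG ratio (reported in the "ICG vs SBG" orientation, with both raw
#' counts), the symmetric fraction among SBGs, the breakpoint-uniformity
#' statistic, and per-run read accounting when run totals are supplied.
#'
#' @param calls A configuration-call tibble from [classify_reads()].
#' @param run_totals Optional named integer vector of per-run read counts
#'   (e.g. reads per sequencing run being merged); their sum is reported.
#' @param ref Optional `aav_reference`; when given (and enough ICG calls
#'   exist) the breakpoint-uniformity test is computed.
#' @param n_bins Bins for the uniformity test.
#' @return An object of class `aav_summary`. Use [generics::tidy()] for the
#'   per-category table and [generics::glance()] for the one-row overview.
#' @export
summarize_population <- function(calls, run_totals = NULL, ref = NULL,
                                 n_bins = 20) {
  n_total <- nrow(calls)
  cat_tbl <- tibble::tibble(category = CATEGORIES) |>
    dplyr::left_join(dplyr::count(calls, .data$category), by = "category") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  fraction = if (n_total > 0) .data$n / n_total else NA_real_)
  qlen <- calls |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      q25 = stats::quantile(.data$read_length, 0.25),
      median = stats::median(.data$read_length),
      q75 = stats::quantile(.data$read_length, 0.75), .groups = "drop")
  n_icg <- sum(calls$category == "ICG", na.rm = TRUE)
  n_sbg <- sum(calls$category %in% c("SBG_5", "SBG_3"), na.rm = TRUE)
  sym_frac <- if (n_sbg > 0) {
    sum(calls$subtype == "SYMMETRIC" &
          calls$category %in% c("SBG_5", "SBG_3"), na.rm = TRUE) / n_sbg
  } else NA_real_
  unif <- NULL
  if (!is.null(ref) && n_icg >= 10) {
    unif <- tryCatch(
      breakpoint_uniformity_test(calls, ref, n_bins = n_bins),
      error = function(e) NULL)
  }
  rt <- NULL
  if (!is.null(run_totals)) {
    rt <- list(per_run = run_totals, total = sum(run_totals))
  }
  structure(
    list(n_reads = n_total, categories = cat_tbl, length_quartiles = qlen,
         icg_count = n_icg, sbg_count = n_sbg,
         icg_sbg_ratio = if (n_sbg > 0) n_icg / n_sbg else NA_real_,
         symmetric_fraction = sym_frac,
         breakpoint_uniformity = unif, run_totals = rt),
    class = "aav_summary"
  )
}

#' @export
print.aav_summary <- function(x, ...) {
  cat("<aav_summary> ", x$n_reads, " reads\n", sep = "")
  print(x$categories)
  cat("ICG/SBG ratio: ",
      ifelse(is.na(x$icg_sbg_ratio), "NA",
             format(x$icg_sbg_ratio, digits = 4)),
      "  (ICG ", x$icg_count, ", SBG ", x$sbg_count, ")\n", sep = "")
  if (!is.na(x$symmetric_fraction)) {
    cat("symmetric fraction among SBGs: ",
        format(x$symmetric_fraction, digits = 4), "\n", sep = "")
  }
  if (!is.null(x$breakpoint_uniformity)) {
    u <- x$breakpoint_uniformity
    cat(sprintf("breakpoint uniformity: X2 = %.2f, df = %d, p = %.3g\n",
                u$statistic, u$parameter, u$p.value))
  }
  if (!is.null(x$run_totals)) {
    cat("run totals: ", paste(x$run_totals$per_run, collapse = " + "),
        " = ", x$run_totals$total, "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname summarize_population
#' @param x An `aav_summary`.
#' @param ... Unused.
#' @export
tidy.aav_summary <- function(x, ...) {
  dplyr::left_join(x$categories, x$length_quartiles, by = "category")
}

#' @rdname summarize_population
#' @export
glance.aav_summary <- function(x, ...) {
  u <- x$breakpoint_uniformity
  tibble::tibble(
    n_reads = x$n_reads,
    icg_count = x$icg_count, sbg_count = x$sbg_count,
    icg_sbg_ratio = x$icg_sbg_ratio,
    symmetric_fraction = x$symmetric_fraction,
    uniformity_chi2 = if (is.null(u)) NA_real_ else unname(u$statistic),
    uniformity_df = if (is.null(u)) NA_integer_ else as.integer(u$parameter),
    uniformity_p = if (is.null(u)) NA_real_ else u$p.value,
    run_total = if (is.null(x$run_totals)) NA_integer_ else
      as.integer(x$run_totals$total)
  )
}

#' Serialize a population summary to JSON
#'
#' @param x An `aav_summary`.
#' @param path Output path.
#' @param seed Seed recorded alongside.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path, seed = NULL) {
  u <- x$breakpoint_uniformity
  out <- list(
    tool = paste0("snapback v",
                  as.character(utils::packageVersion("snapback"))),
    seed = seed,
    n_reads = x$n_reads,
    categories = x$categories,
    length_quartiles = x$length_quartiles,
    icg_count = x$icg_count, sbg_count = x$sbg_count,
    icg_sbg_ratio = x$icg_sbg_ratio,
    symmetric_fraction = x$symmetric_fraction,
    breakpoint_uniformity = if (is.null(u)) NULL else
      list(chi2 = unname(u$statistic), df = unname(u$parameter),
           p = u$p.value),
    run_totals = x$run_totals
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Category and subtype recovery against truth labels
#'
#' Joins configuration calls to a simulated truth table and computes the
#' category confusion matrix, category accuracy, and (over reads whose truth
#' is an SBG) subtype accuracy.
#'
#' @param calls A configuration-call tibble.
#' @param truth A reads/truth tibble with `id` (or `read_id`), `category`,
#'   `subtype`.
#' @return List: `category_accuracy`, `subtype_accuracy`, `confusion`
#'   (tibble truth x called), `n`.
#' @export
recovery_rates <- function(calls, truth) {
  if ("id" %in% names(truth)) truth <- dplyr::rename(truth, read_id = "id")
  j <- dplyr::inner_join(
    dplyr::select(truth, "read_id", truth_category = "category",
                  truth_subtype = "subtype"),
    dplyr::select(calls, "read_id", called_category = "category",
                  called_subtype = "subtype"),
    by = "read_id")
  conf <- dplyr::count(j, .data$truth_category, .data$called_category)
  sbg <- dplyr::filter(j, .data$truth_category %in% c("SBG_5", "SBG_3"))
  list(
    category_accuracy = mean(j$truth_category == j$called_category),
    subtype_accuracy = if (nrow(sbg) > 0) {
      mean(sbg$truth_category == sbg$called_category &
             sbg$truth_subtype == sbg$called_subtype)
    } else NA_real_,
    confusion = conf,
    n = nrow(j)
  )
}
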