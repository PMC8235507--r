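#' Plot the category composition of a population summary
#'
#' Bar chart of per-category read fractions.
#'
#' @param object An `aav_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aav_summary <- function(object, ...) {
  d <- object$categories
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of reads",
                  title = "Genome-configuration composition") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the ICG breakpoint distribution
#'
#' Histogram of incomplete-genome breakpoints over the non-ITR interior; a
#' flat profile is the no-hot-spot (random abortive packaging) expectation.
#'
#' @param calls A configuration-call tibble.
#' @param ref An `aav_reference` (draws the interior limits).
#' @param binwidth Histogram bin width in nt.
#' @return A ggplot object.
#' @export
plot_breakpoints <- function(calls, ref, binwidth = 200) {
  d <- dplyr::filter(calls, .data$category == "ICG", !is.na(.data$breakpoint))
  interior <- ref_interior(ref)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$breakpoint)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = interior[1],
                            fill = "grey40") +
    ggplot2::geom_vline(xintercept = interior, linetype = "dashed") +
    ggplot2::labs(x = "breakpoint (reference coordinate)", y = "ICG reads",
                  title = "Incomplete-genome breakpoints") +
    ggplot2::theme_minimal()
}

#' Plot snapback arm asymmetry
#'
#' Histogram of `|arm_a - arm_b|` (the single-stranded loop length) over SBG
#' calls, split by fold side.
#'
#' @param calls A configuration-call tibble.
#' @param bin_width Bin width in nt.
#' @return A ggplot object.
#' @export
plot_arm_symmetry <- function(calls, bin_width = 100) {
  d <- dplyr::filter(calls, .data$category %in% c("SBG_5", "SBG_3"),
                     !is.na(.data$loop_len))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$loop_len)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            fill = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$category)) +
    ggplot2::labs(x = "|arm_a - arm_b| (nt)", y = "SBG reads",
                  title = "Snapback arm asymmetry") +
    ggplot2::theme_minimal()
}
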