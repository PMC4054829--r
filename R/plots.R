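# ggplot2 visualisations for the main result types. The dashed line at
# fold = 1 is the reference enrichment rate expected under random placement.

#' Plot feature enrichment folds
#'
#' @param object An `hmc_enrichment` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hmc_enrichment <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$fold)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fold enrichment vs random placement") +
    ggplot2::theme_minimal()
}

#' Plot the peak-sharing histogram
#'
#' @param x An `hmc_sharing` object from [classify_peak_sharing()].
#' @return A ggplot of the fraction of peaks at each sharing degree.
#' @export
plot_peak_sharing <- function(x) {
  if (!inherits(x, "hmc_sharing")) abort("`x` must be an hmc_sharing object")
  ggplot2::ggplot(x$histogram,
                  ggplot2::aes(x = factor(.data$degree), y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "samples sharing the peak", y = "fraction of peaks") +
    ggplot2::theme_minimal()
}

#' Plot per-chromosome block representation
#'
#' @param x Output of [chromosome_representation()].
#' @return A ggplot with the fold per chromosome and the reference line at 1.
#' @export
plot_chromosome_representation <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = factor(.data$chrom,
                                             levels = x$chrom),
                                  y = .data$fold)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "fold vs genome share") +
    ggplot2::theme_minimal()
}

#' Plot top GREAT-style terms
#'
#' @param object An `hmc_great` object.
#' @param top_n Terms shown (default 10).
#' @param ... Unused.
#' @return A ggplot of -log10 binomial p for the top-ranked terms.
#' @export
autoplot.hmc_great <- function(object, top_n = 10L, ...) {
  d <- rank_terms(tidy(object), top_n)
  d$term_name <- factor(d$term_name, levels = rev(d$term_name))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term_name,
                                  y = -log10(.data$binom_raw_p))) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 binomial raw p") +
    ggplot2::theme_minimal()
}
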