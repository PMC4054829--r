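# broom-style tidiers for the package's result objects.

#' Tidy an enrichment result
#'
#' @param x An `hmc_enrichment` object.
#' @param ... Unused.
#' @return One row per feature/class with observed and expected bp,
#'   reference fraction and fold enrichment (plus permutation columns when
#'   the null was permuted).
#' @export
tidy.hmc_enrichment <- function(x, ...) x$results

#' @rdname tidy.hmc_enrichment
#' @export
glance.hmc_enrichment <- function(x, ...) {
  tibble(
    n_features = nrow(x$results),
    block_bp = x$block_bp,
    reference_bp = x$reference_bp,
    method = x$method
  )
}

#' Tidy a GREAT-style term-enrichment result
#'
#' @param x An `hmc_great` object.
#' @param ... Unused.
#' @return The full term table in [rank_terms()] order.
#' @export
tidy.hmc_great <- function(x, ...) x$table

#' @rdname tidy.hmc_great
#' @export
glance.hmc_great <- function(x, ...) {
  tibble(
    n_terms = nrow(x$table),
    n_regions = x$n_regions,
    n_hit_genes = x$n_hit_genes,
    universe_n = x$universe_n,
    top_term = x$table$term_id[1]
  )
}

#' Tidy a peak-sharing classification
#'
#' @param x An `hmc_sharing` object.
#' @param ... Unused.
#' @return The per-degree histogram tibble.
#' @export
tidy.hmc_sharing <- function(x, ...) x$histogram

#' @rdname tidy.hmc_sharing
#' @export
glance.hmc_sharing <- function(x, ...) {
  tibble(
    n_samples = x$n_samples,
    n_peaks = x$n_peaks,
    unique_fraction = x$unique_fraction,
    shared_by_all_fraction = x$shared_by_all_fraction
  )
}
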