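# Expression-level classes and developmental expression groups.
#
# Expression matrices are tibbles with a gene_id column plus one column per
# sample (normalized intensities on the linear scale); sample_info maps
# sample_id -> cohort.

check_expression <- function(expr) {
  if (!is.data.frame(expr) || !"gene_id" %in% names(expr)) {
    abort("`expr` must be a data frame with a gene_id column")
  }
  if (anyDuplicated(expr$gene_id)) abort("gene ids must be unique")
  vals <- expr[setdiff(names(expr), "gene_id")]
  if (ncol(vals) == 0) abort("`expr` has no sample columns")
  if (any(vapply(vals, function(v) any(is.na(v)), TRUE))) {
    abort("`expr` must have no missing cells")
  }
  if (any(vapply(vals, function(v) any(v < 0), TRUE))) {
    abort("expression values must be non-negative")
  }
  invisible(expr)
}

#' Read an expression matrix
#'
#' TSV with a header row: first column `gene_id`, remaining columns one per
#' sample.
#'
#' @param path File path.
#' @return An expression tibble.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("expression matrix not found: ", path))
  expr <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", .default = "d"), progress = FALSE)
  check_expression(expr)
  expr
}

#' Per-gene median expression within a cohort
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param sample_info Tibble with columns `sample_id` and `cohort`.
#' @param cohort Cohort to summarize.
#' @return A tibble `gene_id`, `median_expr`.
#' @examples
#' expr <- tibble::tibble(gene_id = "g1", s1 = 2, s2 = 4, s3 = 6)
#' info <- tibble::tibble(sample_id = c("s1", "s2", "s3"), cohort = "fetal")
#' summarize_cohort(expr, info, "fetal")
#' @export
summarize_cohort <- function(expr, sample_info, cohort) {
  check_expression(expr)
  ids <- sample_info$sample_id[sample_info$cohort == cohort]
  if (length(ids) == 0) abort(paste0("unknown cohort: ", cohort))
  missing <- setdiff(ids, names(expr))
  if (length(missing)) {
    abort(paste0("samples missing from expression matrix: ",
                 paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(expr[ids])
  tibble(gene_id = expr$gene_id,
         median_expr = apply(vals, 1, median))
}

# Balanced contiguous tertile assignment of ranks 1..n: gene i (in stable
# order) goes to class ceiling(3 i / n), giving sizes that differ by at most
# one.
tertile_of <- function(idx, n) ceiling(3 * idx / n)

#' Classify genes into silent/low/intermediate/high expression
#'
#' Genes with median expression below `silent_threshold` are silent; the
#' remaining genes are split into tertiles of the cohort median (low /
#' intermediate / high), with ties broken by stable gene-id order so class
#' sizes are always balanced to within one gene.
#'
#' @param medians Tibble `gene_id`, `median_expr` (from
#'   [summarize_cohort()]).
#' @param silent_threshold Silence cutoff on the linear expression scale;
#'   defaults to the 5th percentile of the supplied medians.
#' @return A tibble `gene_id`, `median_expr`, `level` (factor silent < low <
#'   intermediate < high).
#' @export
classify_levels <- function(medians, silent_threshold = NULL) {
  if (!all(c("gene_id", "median_expr") %in% names(medians))) {
    abort("`medians` needs columns gene_id and median_expr")
  }
  if (is.null(silent_threshold)) {
    silent_threshold <- as.numeric(quantile(medians$median_expr, 0.05))
  }
  silent <- medians$median_expr < silent_threshold
  if (all(silent)) abort("all genes are silent at this threshold")
  if (sum(!silent) < 3) abort("need at least 3 non-silent genes for tertiles")
  lv <- c("silent", "low", "intermediate", "high")
  level <- rep("silent", nrow(medians))
  exprd <- which(!silent)
  ord <- exprd[order(medians$median_expr[exprd], medians$gene_id[exprd])]
  level[ord] <- lv[1 + tertile_of(seq_along(ord), length(ord))]
  tibble(gene_id = medians$gene_id,
         median_expr = medians$median_expr,
         level = factor(level, levels = lv))
}

#' Assign developmental expression groups I-V
#'
#' Group I: expressed in the fetal cohort, silent in the adult; group V the
#' mirror image. Among genes expressed in both cohorts, group II has fetal
#' expression at least `fold` times the adult, group IV the mirror image,
#' and group III the rest. Genes silent in both cohorts are `unassigned`.
#' All comparisons are on the linear scale of the normalized values.
#'
#' @param fetal_medians,adult_medians Tibbles `gene_id`, `median_expr` over
#'   the same gene universe.
#' @param silent_threshold Silence cutoff (linear scale).
#' @param fold Developmental fold-change boundary (> 1; default 2).
#' @return A tibble `gene_id`, `fetal_median`, `adult_median`, `group`
#'   (factor I, II, III, IV, V, unassigned).
#' @examples
#' f <- tibble::tibble(gene_id = c("a", "b"), median_expr = c(8, 10))
#' a <- tibble::tibble(gene_id = c("a", "b"), median_expr = c(0.1, 4))
#' assign_groups(f, a, silent_threshold = 1)
#' @export
assign_groups <- function(fetal_medians, adult_medians, silent_threshold,
                          fold = 2) {
  if (fold <= 1) abort("`fold` must be > 1")
  if (!setequal(fetal_medians$gene_id, adult_medians$gene_id) ||
      nrow(fetal_medians) != nrow(adult_medians)) {
    abort("fetal and adult medians must cover the same gene universe")
  }
  j <- dplyr::inner_join(
    dplyr::rename(fetal_medians, fetal_median = "median_expr"),
    dplyr::rename(adult_medians, adult_median = "median_expr"),
    by = "gene_id"
  )
  fe <- j$fetal_median >= silent_threshold
  ae <- j$adult_median >= silent_threshold
  group <- rep("unassigned", nrow(j))
  group[fe & !ae] <- "I"
  group[!fe & ae] <- "V"
  both <- fe & ae
  group[both & j$fetal_median >= fold * j$adult_median] <- "II"
  group[both & j$adult_median >= fold * j$fetal_median] <- "IV"
  group[both & group == "unassigned"] <- "III"
  j$group <- factor(group, levels = c("I", "II", "III", "IV", "V",
                                      "unassigned"))
  j
}

#' Full expression classification for both cohorts
#'
#' Runs [summarize_cohort()], [classify_levels()] and [assign_groups()] for
#' a fetal/adult study in one call.
#'
#' @param expr Expression tibble.
#' @param sample_info Tibble `sample_id`, `cohort` with cohorts `"fetal"`
#'   and `"adult"`.
#' @param silent_threshold Silence cutoff; `NULL` uses each call's
#'   percentile default.
#' @param fold Developmental fold boundary.
#' @return A tibble with per-gene medians, per-cohort levels and the
#'   developmental group.
#' @export
classify_expression <- function(expr, sample_info, silent_threshold = NULL,
                                fold = 2) {
  fm <- summarize_cohort(expr, sample_info, "fetal")
  am <- summarize_cohort(expr, sample_info, "adult")
  thr_f <- silent_threshold %||%
    as.numeric(quantile(fm$median_expr, 0.05))
  thr_a <- silent_threshold %||%
    as.numeric(quantile(am$median_expr, 0.05))
  lf <- classify_levels(fm, thr_f)
  la <- classify_levels(am, thr_a)
  groups <- assign_groups(fm, am, silent_threshold = min(thr_f, thr_a),
                          fold = fold)
  groups %>%
    dplyr::left_join(dplyr::select(lf, "gene_id", level_fetal = "level"),
                     by = "gene_id") %>%
    dplyr::left_join(dplyr::select(la, "gene_id", level_adult = "level"),
                     by = "gene_id")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
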