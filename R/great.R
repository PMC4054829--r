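# GREAT-style regulatory domains and term enrichment: each gene gets a
# basal domain around its TSS (5 kb upstream / 1 kb downstream by default)
# extended in both directions up to 1 Mb, stopping at the nearest gene's
# basal domain; regions (blocks) are assigned to domains by their midpoint,
# and term enrichment combines a region-based binomial test with a
# gene-based hypergeometric test.

check_gene_models <- function(genes, genome = NULL) {
  need <- c("gene_id", "chrom", "strand", "tss", "start", "end")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    abort("gene models need columns gene_id, chrom, strand, tss, start, end")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicate gene id(s): ",
                 paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                       collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  if (!is.null(genome)) {
    check_intervals(genes[c("chrom", "start", "end")], genome, "genes")
  }
  invisible(genes)
}

#' Read and write gene model tables
#'
#' Gene models are TSVs with header columns `gene_id`, `chrom`, `strand`,
#' `tss`, `start`, `end` (body coordinates 0-based half-open; `tss` is the
#' 0-based transcription start coordinate).
#'
#' @param path File path.
#' @return `read_gene_models()` returns a gene-model tibble;
#'   `write_gene_models()` returns `path` invisibly.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(paste0("gene model table not found: ", path))
  g <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", chrom = "c", strand = "c", tss = "d", start = "d",
    end = "d"), progress = FALSE)
  check_gene_models(g)
  g
}

#' @rdname read_gene_models
#' @param genes Gene-model tibble.
#' @export
write_gene_models <- function(genes, path) {
  check_gene_models(genes)
  readr::write_tsv(
    genes[c("gene_id", "chrom", "strand", "tss", "start", "end")], path)
  invisible(path)
}

#' Read a term-membership table
#'
#' TSV with header columns `term_id`, `term_name`, `gene_id`; one row per
#' (term, gene) membership.
#'
#' @param path File path.
#' @return A tibble with those three columns.
#' @export
read_terms <- function(path) {
  if (!file.exists(path)) abort(paste0("term table not found: ", path))
  t <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!all(c("term_id", "term_name", "gene_id") %in% names(t))) {
    abort("terms need columns term_id, term_name, gene_id")
  }
  t
}

#' Build gene regulatory domains (basal plus extension)
#'
#' The basal domain spans `basal_up` bp upstream and `basal_down` bp
#' downstream of the TSS, oriented by strand. The extended domain grows from
#' the basal domain in each direction until the nearest neighboring gene's
#' basal domain, the chromosome end, or `max_extension` bp, whichever comes
#' first; a gene's own basal domain is never truncated, and extensions never
#' invade another gene's basal domain.
#'
#' @param genes Gene-model tibble.
#' @param genome Genome tibble.
#' @param basal_up,basal_down Basal domain extent upstream/downstream of the
#'   TSS in bp (defaults 5000 and 1000).
#' @param max_extension Maximum extension beyond the basal domain in bp
#'   (default 1e6).
#' @return A tibble `gene_id`, `chrom`, `strand`, `basal_start`,
#'   `basal_end`, `ext_start`, `ext_end`.
#' @export
build_regulatory_domains <- function(genes, genome, basal_up = 5000L,
                                     basal_down = 1000L,
                                     max_extension = 1e6) {
  check_gene_models(genes, genome)
  check_genome(genome)
  sizes <- genome$size[match(genes$chrom, genome$chrom)]
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, genes$tss - basal_up, genes$tss - basal_down)
  basal_end <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up)
  basal_start <- pmax(0, basal_start)
  basal_end <- pmin(sizes, basal_end)
  out <- tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    basal_start = basal_start, basal_end = basal_end,
    ext_start = NA_real_, ext_end = NA_real_
  )
  for (chr in unique(out$chrom)) {
    i <- which(out$chrom == chr)
    size <- genome$size[genome$chrom == chr]
    for (k in i) {
      others <- setdiff(i, k)
      # a neighboring basal domain sticking out on either side caps the
      # extension there (clamped so the gene's own basal is never truncated)
      left_nb <- others[out$basal_start[others] < out$basal_start[k]]
      left_lim <- if (length(left_nb)) {
        max(pmin(out$basal_end[left_nb], out$basal_start[k]))
      } else 0
      right_nb <- others[out$basal_end[others] > out$basal_end[k]]
      right_lim <- if (length(right_nb)) {
        min(pmax(out$basal_start[right_nb], out$basal_end[k]))
      } else size
      es <- max(out$basal_start[k] - max_extension, left_lim, 0)
      ee <- min(out$basal_end[k] + max_extension, right_lim, size)
      out$ext_start[k] <- min(es, out$basal_start[k])
      out$ext_end[k] <- max(ee, out$basal_end[k])
    }
  }
  out
}

region_midpoints <- function(regions) {
  check_interval_frame(regions, "regions")
  tibble(chrom = regions$chrom,
         start = regions$start + (regions$end - regions$start) %/% 2) %>%
    dplyr::mutate(end = .data$start + 1)
}

#' Region-based binomial enrichment test
#'
#' Each region is reduced to its midpoint; `k` of the `n` midpoints fall in
#' the (normalized) term domains, whose genome fraction is `p0`. The raw
#' p-value is the upper tail P(X >= k) for X ~ Binomial(n, p0), and fold
#' enrichment is k / (n p0).
#'
#' @param regions Interval tibble of regions (e.g. cohort-only blocks).
#' @param term_domains Interval tibble of the term's regulatory domains.
#' @param genome Genome tibble.
#' @param assign `"midpoint"` (default, GREAT's convention) or `"any"`
#'   (count regions with any overlap).
#' @return A one-row tibble `n_regions`, `k`, `p0`, `raw_p`, `fold`.
#' @export
binomial_region_test <- function(regions, term_domains, genome,
                                 assign = c("midpoint", "any")) {
  assign <- match.arg(assign)
  check_genome(genome)
  n <- nrow(regions)
  if (n == 0) abort("no regions to test")
  dom <- normalize_intervals(term_domains, genome)
  p0 <- interval_bp(dom) / genome_size(genome)
  probe <- if (assign == "midpoint") region_midpoints(regions) else regions
  levels <- chrom_levels(dplyr::bind_rows(probe, dom), genome)
  hits <- GenomicRanges::findOverlaps(ivl_to_gr(probe, genome, levels),
                                      ivl_to_gr(dom, genome, levels))
  k <- length(unique(S4Vectors::queryHits(hits)))
  if (p0 == 0 && k > 0) {
    abort("term domains cover zero bp but regions hit them: annotation inconsistency")
  }
  tibble(
    n_regions = n, k = k, p0 = p0,
    raw_p = if (k == 0) 1 else stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
    fold = if (p0 > 0) k / (n * p0) else 0
  )
}

#' Gene-based hypergeometric enrichment test
#'
#' Tests whether the overlap k between the hit genes and the term genes is
#' larger than expected when drawing `|hit_genes|` genes from the universe:
#' raw p = P(X >= k) for X ~ Hypergeometric(N, K, n). Fold is
#' (k/n) / (K/N).
#'
#' @param hit_genes Character vector of genes carrying the signal.
#' @param term_genes Character vector of the term's genes.
#' @param universe Character vector of all analyzed genes.
#' @return A one-row tibble `N`, `K`, `n`, `k`, `raw_p`, `fold`.
#' @export
hypergeometric_gene_test <- function(hit_genes, term_genes, universe) {
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (N == 0) abort("empty gene universe")
  hit_genes <- unique(as.character(hit_genes))
  term_genes <- unique(as.character(term_genes))
  if (!all(hit_genes %in% universe)) abort("hit genes outside the universe")
  if (!all(term_genes %in% universe)) abort("term genes outside the universe")
  K <- length(term_genes)
  n <- length(hit_genes)
  k <- length(intersect(hit_genes, term_genes))
  tibble(
    N = N, K = K, n = n, k = k,
    raw_p = if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n,
                                             lower.tail = FALSE),
    fold = if (n > 0 && K > 0) (k / n) / (K / N) else 0
  )
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up q-values; monotone non-decreasing in p-rank and never below the
#' raw p-value.
#'
#' @param raw_ps Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(raw_ps) {
  if (any(is.na(raw_ps)) || any(raw_ps < 0) || any(raw_ps > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(raw_ps, method = "BH")
}

#' Rank term-enrichment rows
#'
#' Sorts ascending by the binomial raw p-value, breaking ties by term id,
#' and keeps the top `top_n` rows.
#'
#' @param rows Term-enrichment tibble (needs `binom_raw_p` and `term_id`).
#' @param top_n Number of rows to keep (default 10).
#' @return The sorted, truncated tibble.
#' @export
rank_terms <- function(rows, top_n = 10L) {
  if (!all(c("term_id", "binom_raw_p") %in% names(rows))) {
    abort("`rows` needs columns term_id and binom_raw_p")
  }
  rows %>%
    dplyr::arrange(.data$binom_raw_p, .data$term_id) %>%
    dplyr::slice_head(n = top_n)
}

#' GREAT-style term enrichment of a region set
#'
#' Builds regulatory domains for all genes, assigns regions to genes by
#' midpoint (or any overlap), and scores every term with both the
#' region-based binomial test (against the term's pooled, normalized
#' domains) and the gene-based hypergeometric test (hit genes = genes whose
#' extended domain contains at least one assigned region). FDR q-values are
#' Benjamini-Hochberg within each test family.
#'
#' @param regions Interval tibble (e.g. cohort-only blocks).
#' @param genes Gene-model tibble.
#' @param terms Term-membership tibble (`term_id`, `term_name`, `gene_id`).
#' @param genome Genome tibble.
#' @param basal_up,basal_down,max_extension Domain parameters, see
#'   [build_regulatory_domains()].
#' @param assign Region-to-domain assignment rule (`"midpoint"` or
#'   `"any"`).
#' @return An object of class `hmc_great`; `tidy()` returns the full term
#'   table (`term_id`, `term_name`, `binom_raw_p`, `binom_fdr_q`,
#'   `binom_fold`, `hyper_raw_p`, `hyper_fdr_q`, `hyper_fold`, plus the test
#'   counts), sorted by [rank_terms()] order.
#' @export
great_enrichment <- function(regions, genes, terms, genome,
                             basal_up = 5000L, basal_down = 1000L,
                             max_extension = 1e6,
                             assign = c("midpoint", "any")) {
  assign <- match.arg(assign)
  check_gene_models(genes, genome)
  if (!all(c("term_id", "term_name", "gene_id") %in% names(terms))) {
    abort("terms need columns term_id, term_name, gene_id")
  }
  unknown <- setdiff(unique(terms$gene_id), genes$gene_id)
  if (length(unknown)) {
    abort(paste0("term gene(s) absent from gene models: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (nrow(regions) == 0) abort("no regions to test")
  domains <- build_regulatory_domains(genes, genome, basal_up, basal_down,
                                      max_extension)
  dom_ivl <- tibble(chrom = domains$chrom, start = domains$ext_start,
                    end = domains$ext_end, gene_id = domains$gene_id)
  probe <- if (assign == "midpoint") region_midpoints(regions) else {
    regions[c("chrom", "start", "end")]
  }
  levels <- genome$chrom
  hits <- GenomicRanges::findOverlaps(ivl_to_gr(probe, genome, levels),
                                      ivl_to_gr(dom_ivl, genome, levels))
  hit_genes <- unique(dom_ivl$gene_id[S4Vectors::subjectHits(hits)])
  universe <- genes$gene_id
  term_tbl <- terms %>%
    dplyr::distinct(.data$term_id, .data$term_name) %>%
    dplyr::arrange(.data$term_id)
  rows <- purrr::pmap(term_tbl, function(term_id, term_name) {
    tg <- unique(terms$gene_id[terms$term_id == term_id])
    td <- dom_ivl[dom_ivl$gene_id %in% tg, c("chrom", "start", "end")]
    bt <- binomial_region_test(regions, td, genome, assign = assign)
    ht <- hypergeometric_gene_test(hit_genes, tg, universe)
    tibble(
      term_id = term_id, term_name = term_name,
      n_regions = bt$n_regions, k_regions = bt$k, p0 = bt$p0,
      binom_raw_p = bt$raw_p, binom_fold = bt$fold,
      n_hit_genes = ht$n, k_genes = ht$k, n_term_genes = ht$K,
      hyper_raw_p = ht$raw_p, hyper_fold = ht$fold
    )
  })
  tab <- dplyr::bind_rows(rows) %>%
    dplyr::mutate(
      binom_fdr_q = bh_fdr(.data$binom_raw_p),
      hyper_fdr_q = bh_fdr(.data$hyper_raw_p)
    )
  tab <- rank_terms(tab, top_n = nrow(tab))
  structure(
    list(table = tab, n_regions = nrow(regions),
         n_hit_genes = length(hit_genes), universe_n = length(universe),
         assign = assign),
    class = "hmc_great"
  )
}

#' @export
print.hmc_great <- function(x, ...) {
  cat(sprintf(
    "GREAT-style term enrichment: %d regions, %d/%d hit genes (%s assignment)\n",
    x$n_regions, x$n_hit_genes, x$universe_n, x$assign))
  print(x$table, ...)
  invisible(x)
}
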