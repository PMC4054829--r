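# Enrichment of block sets in feature tracks against a random-placement
# null. The statistic is base-pair weighted throughout: fold enrichment is
# (observed bp in feature / total block bp) / (feature bp / genome bp), so a
# dashed reference line at fold = 1 marks "no enrichment".

new_hmc_enrichment <- function(results, block_bp, reference_bp, method,
                               reference = "genome") {
  structure(
    list(results = results, block_bp = block_bp, reference_bp = reference_bp,
         method = method, reference = reference),
    class = "hmc_enrichment"
  )
}

#' @export
print.hmc_enrichment <- function(x, ...) {
  cat(sprintf("5hmC block enrichment (%s null; %s bp of blocks vs %s bp %s)\n",
              x$method, format(x$block_bp, big.mark = ","),
              format(x$reference_bp, big.mark = ","), x$reference))
  print(x$results, ...)
  invisible(x)
}

as_feature_list <- function(features, name = "feature") {
  if (is.data.frame(features)) {
    features <- setNames(list(features), name)
  }
  if (is.null(names(features)) || any(!nzchar(names(features)))) {
    abort("`features` must be a named list of interval tibbles")
  }
  features
}

#' Analytic feature enrichment of a block set
#'
#' Under a null of uniform random placement of the blocks in the genome, the
#' expected bp of block-feature overlap is `block_bp * feature_fraction`.
#' Fold enrichment is the ratio of observed to expected overlap.
#'
#' @param blocks Block/interval tibble (total bp must be > 0).
#' @param features A named list of feature interval tibbles, or a single
#'   tibble (then named via `name`).
#' @param genome Genome tibble.
#' @param name Feature name used when `features` is a single tibble.
#' @return An `hmc_enrichment` object; `tidy()` returns one row per feature
#'   with `feature`, `observed_bp`, `expected_bp`, `feature_fraction`,
#'   `fold`.
#' @examples
#' genome <- hmc_genome("chr1", 1000)
#' blocks <- tibble::tibble(chrom = "chr1", start = c(0, 500), end = c(100, 600))
#' cgi <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' tidy(analytic_enrichment(blocks, cgi, genome, name = "cgi"))
#' @export
analytic_enrichment <- function(blocks, features, genome, name = "feature") {
  check_genome(genome)
  features <- as_feature_list(features, name)
  blocks <- normalize_intervals(blocks, genome)
  block_bp <- interval_bp(blocks)
  if (block_bp == 0) abort("empty block set: no bp to test for enrichment")
  gsize <- genome_size(genome)
  rows <- purrr::imap(features, function(f, nm) {
    f <- normalize_intervals(f, genome)
    fbp <- interval_bp(f)
    if (fbp == 0) abort(paste0("empty feature track: ", nm))
    obs <- interval_bp(intersect_intervals(blocks, f, genome))
    frac <- fbp / gsize
    tibble(
      feature = nm,
      observed_bp = obs,
      expected_bp = block_bp * frac,
      feature_fraction = frac,
      fold = (obs / block_bp) / frac
    )
  })
  new_hmc_enrichment(dplyr::bind_rows(rows), block_bp, gsize, "analytic")
}

# Vectorized uniform placement: n_perm independent placements of all block
# lengths. Chromosome chosen with probability proportional to length among
# chromosomes the block fits on; position uniform within the chromosome.
place_random_blocks <- function(lengths, genome, n_perm = 1L) {
  n <- length(lengths)
  if (n == 0) abort("no blocks to place")
  if (max(lengths) > max(genome$size)) {
    abort(sprintf("block of %d bp longer than every chromosome",
                  max(lengths)))
  }
  total <- n * n_perm
  len <- rep(lengths, times = n_perm)
  fits_all <- max(lengths) <= min(genome$size)
  if (fits_all) {
    ci <- sample.int(nrow(genome), total, replace = TRUE, prob = genome$size)
  } else {
    ci <- integer(total)
    for (l in unique(lengths)) {
      sel <- which(len == l)
      ok <- which(genome$size >= l)
      ci[sel] <- ok[sample.int(length(ok), length(sel), replace = TRUE,
                               prob = genome$size[ok])]
    }
  }
  start <- floor(runif(total) * (genome$size[ci] - len + 1))
  tibble(
    perm = rep(seq_len(n_perm), each = n),
    chrom = genome$chrom[ci],
    start = start,
    end = start + len
  )
}

#' Uniform random placement of intervals in a genome
#'
#' Draws one placement of the given interval lengths uniformly at random:
#' chromosome with probability proportional to its length (among chromosomes
#' the interval fits on), position uniform within the chromosome. Placed
#' intervals may overlap each other. This is the package's random-placement
#' null, exposed directly so calibration checks can reuse it.
#'
#' @param lengths Integer vector of interval lengths in bp.
#' @param genome Genome tibble.
#' @param seed Optional integer seed for reproducibility.
#' @return An interval tibble (not normalized; one row per placed interval).
#' @export
random_placement <- function(lengths, genome, seed = NULL) {
  check_genome(genome)
  draw <- function() place_random_blocks(lengths, genome, 1L)[
    c("chrom", "start", "end")]
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Permutation feature enrichment of a block set
#'
#' Each permutation places every block, length-preserved, uniformly at
#' random in the genome (see [random_placement()]; placed blocks may
#' overlap). Fold is observed overlap bp over the mean permuted overlap bp;
#' the two-sided empirical p-value uses the (r + 1)/(n + 1) estimator so it
#' is never exactly zero.
#'
#' @param blocks Block/interval tibble.
#' @param feature A single feature interval tibble.
#' @param genome Genome tibble.
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param name Feature name for the output.
#' @return An `hmc_enrichment` object whose `results` tibble has, in
#'   addition to the analytic columns, `perm_mean_bp`, `perm_sd_bp`,
#'   `null_p`, `n_perm` and `seed`.
#' @export
permutation_enrichment <- function(blocks, feature, genome, n_perm = 1000L,
                                   seed = 1L, name = "feature") {
  check_genome(genome)
  n_perm <- as.integer(n_perm)
  if (n_perm < 100) abort("`n_perm` must be at least 100")
  blocks <- normalize_intervals(blocks, genome)
  if (nrow(blocks) == 0) abort("empty block set: no bp to test for enrichment")
  feature <- normalize_intervals(feature, genome)
  if (nrow(feature) == 0) abort(paste0("empty feature track: ", name))
  lengths <- as.integer(blocks$end - blocks$start)
  obs <- interval_bp(intersect_intervals(blocks, feature, genome))
  placed <- withr::with_seed(as.integer(seed),
                             place_random_blocks(lengths, genome, n_perm))
  # overlap bp of each placed block with the feature, summed per permutation
  pgr <- ivl_to_gr(placed, genome)
  fgr <- ivl_to_gr(feature, genome)
  hits <- GenomicRanges::findOverlaps(pgr, fgr)
  ov <- GenomicRanges::width(IRanges::pintersect(
    pgr[S4Vectors::queryHits(hits)], fgr[S4Vectors::subjectHits(hits)]))
  perm_bp <- numeric(n_perm)
  if (length(ov)) {
    by_perm <- tapply(as.numeric(ov), placed$perm[S4Vectors::queryHits(hits)], sum)
    perm_bp[as.integer(names(by_perm))] <- as.numeric(by_perm)
  }
  m <- mean(perm_bp)
  p_ge <- (sum(perm_bp >= obs) + 1) / (n_perm + 1)
  p_le <- (sum(perm_bp <= obs) + 1) / (n_perm + 1)
  block_bp <- interval_bp(blocks)
  feature_bp <- interval_bp(feature)
  res <- tibble(
    feature = name,
    observed_bp = obs,
    expected_bp = m,
    feature_fraction = feature_bp / genome_size(genome),
    fold = if (m > 0) obs / m else NA_real_,
    perm_mean_bp = m,
    perm_sd_bp = stats::sd(perm_bp),
    null_p = min(1, 2 * min(p_ge, p_le)),
    n_perm = n_perm,
    seed = as.integer(seed)
  )
  new_hmc_enrichment(res, block_bp, genome_size(genome), "permutation")
}

#' Per-chromosome representation of a block set
#'
#' For each chromosome, fold = (block bp on the chromosome / total block bp)
#' / (chromosome length / genome length). Values above 1 mark chromosomes
#' over-represented among the blocks.
#'
#' @param blocks Block/interval tibble.
#' @param genome Genome tibble.
#' @return A tibble: `chrom`, `chrom_bp`, `block_bp`, `expected_share`,
#'   `fold`.
#' @export
chromosome_representation <- function(blocks, genome) {
  check_genome(genome)
  blocks <- normalize_intervals(blocks, genome)
  total <- interval_bp(blocks)
  if (total == 0) abort("empty block set")
  per <- blocks %>%
    dplyr::mutate(len = .data$end - .data$start) %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::summarise(block_bp = sum(.data$len), .groups = "drop")
  genome %>%
    dplyr::left_join(per, by = "chrom") %>%
    dplyr::mutate(
      block_bp = dplyr::coalesce(.data$block_bp, 0),
      expected_share = .data$size / sum(.data$size),
      fold = (.data$block_bp / total) / .data$expected_share
    ) %>%
    dplyr::select(chrom = "chrom", chrom_bp = "size", "block_bp",
                  "expected_share", "fold")
}

#' Enrichment of blocks in expression-defined gene classes
#'
#' The reference space is the union of the analyzed genes' bodies; per
#' class, fold = (block bp in that class's gene bodies / block bp in all
#' analyzed gene bodies) / (class gene-body bp / all gene-body bp). Classes
#' whose gene bodies cover zero bp are dropped with a warning.
#'
#' @param blocks Block/interval tibble.
#' @param classes Tibble with columns `gene_id` and `class` (any labels:
#'   expression levels, developmental groups, ...).
#' @param gene_bodies Tibble with columns `gene_id`, `chrom`, `start`,
#'   `end`.
#' @param genome Optional genome tibble.
#' @return An `hmc_enrichment` object with one row per class.
#' @export
expression_class_enrichment <- function(blocks, classes, gene_bodies,
                                        genome = NULL) {
  if (!all(c("gene_id", "class") %in% names(classes))) {
    abort("`classes` needs columns gene_id and class")
  }
  check_interval_frame(gene_bodies, "gene_bodies")
  if (!"gene_id" %in% names(gene_bodies)) {
    abort("`gene_bodies` needs a gene_id column")
  }
  bodies <- dplyr::inner_join(gene_bodies, classes, by = "gene_id")
  all_bodies <- normalize_intervals(bodies, genome)
  total_body_bp <- interval_bp(all_bodies)
  if (total_body_bp == 0) abort("gene bodies cover zero bp")
  blocks <- normalize_intervals(blocks, genome)
  obs_all <- interval_bp(intersect_intervals(blocks, all_bodies, genome))
  cls <- unique(as.character(bodies$class))
  rows <- purrr::map(cls, function(cl) {
    cb <- normalize_intervals(bodies[bodies$class == cl, ], genome)
    cbp <- interval_bp(cb)
    if (cbp == 0) {
      warn(paste0("class ", cl, " has zero gene-body bp; dropped"))
      return(NULL)
    }
    obs <- interval_bp(intersect_intervals(blocks, cb, genome))
    tibble(
      feature = cl,
      observed_bp = obs,
      expected_bp = obs_all * cbp / total_body_bp,
      feature_fraction = cbp / total_body_bp,
      fold = if (obs_all > 0) (obs / obs_all) / (cbp / total_body_bp) else NA_real_
    )
  })
  res <- dplyr::bind_rows(rows)
  res <- res[order(res$feature), , drop = FALSE]
  new_hmc_enrichment(res, obs_all, total_body_bp, "analytic",
                     reference = "of analyzed gene bodies")
}

#' Enrichment of cohort-only blocks in developmental gene groups I-V
#'
#' Convenience wrapper around [expression_class_enrichment()] restricted to
#' the five developmental expression groups (I fetal-specific, II
#' fetal-biased, III non-developmental, IV adult-biased, V adult-specific).
#'
#' @param blocks Cohort-only block tibble.
#' @param groups Tibble with columns `gene_id` and `group` (values among
#'   I-V; other labels, e.g. "unassigned", are excluded).
#' @param gene_bodies Tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param genome Optional genome tibble.
#' @return An `hmc_enrichment` object with one row per group present.
#' @export
developmental_group_enrichment <- function(blocks, groups, gene_bodies,
                                           genome = NULL) {
  if (!all(c("gene_id", "group") %in% names(groups))) {
    abort("`groups` needs columns gene_id and group")
  }
  keep <- groups[groups$group %in% c("I", "II", "III", "IV", "V"), ]
  classes <- tibble(gene_id = keep$gene_id, class = as.character(keep$group))
  expression_class_enrichment(blocks, classes, gene_bodies, genome)
}

#' Derive CpG-island shores
#'
#' Shores are the 2 kb flanks on each side of a CpG island, minus the
#' islands themselves (so island and shore tracks are disjoint).
#'
#' @param cgi CpG-island interval tibble.
#' @param genome Genome tibble (flanks are clipped at chromosome ends).
#' @param flank Flank width in bp (default 2000).
#' @return A normalized interval tibble of shores.
#' @export
cgi_shores <- function(cgi, genome, flank = 2000L) {
  check_genome(genome)
  cgi <- normalize_intervals(cgi, genome)
  if (nrow(cgi) == 0) return(empty_intervals())
  sizes <- genome$size[match(cgi$chrom, genome$chrom)]
  flanks <- dplyr::bind_rows(
    tibble(chrom = cgi$chrom, start = pmax(0, cgi$start - flank),
           end = cgi$start),
    tibble(chrom = cgi$chrom, start = cgi$end,
           end = pmin(sizes, cgi$end + flank))
  )
  flanks <- flanks[flanks$start < flanks$end, ]
  subtract_intervals(normalize_intervals(flanks, genome), cgi, genome)
}
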