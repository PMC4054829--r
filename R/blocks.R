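# Consensus 5hmC block construction and cohort comparison.
#
# Peak tables are long tibbles: one row per peak, with columns
# chrom/start/end, sample_id, optionally cohort and reads.

check_peaks <- function(peaks, genome = NULL) {
  check_interval_frame(peaks, "peaks")
  if (!"sample_id" %in% names(peaks)) {
    abort("`peaks` must have a `sample_id` column")
  }
  check_intervals(peaks, genome, "peaks")
  invisible(peaks)
}

# Merge overlapping/bookended peaks within each sample; reads are summed over
# merged peaks.
normalize_peaks <- function(peaks, genome = NULL) {
  check_peaks(peaks, genome)
  if (nrow(peaks) == 0) return(peaks)
  has_reads <- "reads" %in% names(peaks)
  has_cohort <- "cohort" %in% names(peaks)
  split_cols <- c("sample_id", if (has_cohort) "cohort")
  parts <- dplyr::group_split(dplyr::group_by(
    peaks, dplyr::across(dplyr::all_of(split_cols))))
  out <- lapply(parts, function(p) {
    gr <- ivl_to_gr(p, genome)
    red <- GenomicRanges::reduce(gr)
    ivl <- gr_to_ivl(red)
    ivl$sample_id <- p$sample_id[1]
    if (has_cohort) ivl$cohort <- p$cohort[1]
    if (has_reads) {
      # reduce() returns sorted ranges, matching gr_to_ivl()'s row order
      hits <- GenomicRanges::findOverlaps(red, gr)
      agg <- tapply(p$reads[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), sum)
      reads <- numeric(length(red))
      reads[as.integer(names(agg))] <- as.numeric(agg)
      ivl$reads <- reads
    }
    ivl
  })
  dplyr::bind_rows(out)
}

#' Read a cohort manifest
#'
#' The manifest is a TSV with header columns `sample_id`, `cohort`,
#' `bed_path` (paths relative to the manifest's directory or absolute).
#'
#' @param path Manifest path.
#' @return A tibble with columns `sample_id`, `cohort`, `bed_path`
#'   (absolute paths).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("sample_id", "cohort", "bed_path")
  if (!all(need %in% names(m))) {
    abort("manifest needs columns sample_id, cohort, bed_path")
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$bed_path)
  m$bed_path[rel] <- file.path(dirname(path), m$bed_path[rel])
  m[need]
}

#' Read per-sample peak BED files listed in a manifest
#'
#' @param manifest A manifest tibble from [read_manifest()], or a path to one.
#' @param genome Optional genome tibble for bounds checking.
#' @return A long peak tibble: `chrom`, `start`, `end`, `reads` (from the BED
#'   score column when present), `sample_id`, `cohort`.
#' @export
read_peak_sets <- function(manifest, genome = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  sets <- purrr::pmap(manifest, function(sample_id, cohort, bed_path) {
    if (!file.exists(bed_path)) {
      abort(paste0("peak BED for sample ", sample_id, " not found: ", bed_path))
    }
    b <- read_bed(bed_path, genome)
    if ("score" %in% names(b)) b <- dplyr::rename(b, reads = "score")
    b$sample_id <- sample_id
    b$cohort <- cohort
    b
  })
  dplyr::bind_rows(sets)
}

#' Call consensus 5hmC blocks from per-sample peaks
#'
#' A block is a maximal genomic interval where at least `min_support` samples
#' of the cohort show peak occupancy, computed from the per-base support
#' profile. Peaks are normalized per sample first, so a sample contributes at
#' most 1 to the support of any base.
#'
#' @param peaks Long peak tibble (one cohort; a `cohort` column with more
#'   than one value is an error).
#' @param min_support Minimum number of supporting samples per base
#'   (default 2).
#' @param genome Optional genome tibble.
#' @param metrics If `TRUE` (default), fill per-block occupancy metrics via
#'   [block_metrics()].
#' @param clip Passed to [block_metrics()]: count only the in-block portion
#'   of each contributing peak instead of its full length.
#'
#' @return A block tibble: `chrom`, `start`, `end` and (with
#'   `metrics = TRUE`) `n_positive`, `sum_peak_bp`, `sum_reads`, carrying
#'   attributes `cohort` and `min_support`. If fewer samples than
#'   `min_support` are supplied the result is empty, with a warning.
#' @examples
#' pk <- tibble::tibble(
#'   chrom = "chr1", start = c(100, 150), end = c(200, 250),
#'   sample_id = c("s1", "s2")
#' )
#' call_blocks(pk, min_support = 2)
#' @export
call_blocks <- function(peaks, min_support = 2L, genome = NULL,
                        metrics = TRUE, clip = FALSE) {
  check_peaks(peaks, genome)
  min_support <- as.integer(min_support)
  if (min_support < 1) abort("`min_support` must be >= 1")
  cohort <- NA_character_
  if ("cohort" %in% names(peaks) && nrow(peaks) > 0) {
    cohorts <- unique(peaks$cohort)
    if (length(cohorts) > 1) {
      abort(paste0("peaks mix cohorts: ", paste(cohorts, collapse = ", "),
                   "; call blocks one cohort at a time"))
    }
    cohort <- cohorts
  }
  n_samples <- dplyr::n_distinct(peaks$sample_id)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_positive = integer(), sum_peak_bp = numeric(),
                  sum_reads = numeric())
  if (n_samples < min_support) {
    warn(sprintf("only %d sample(s) for min_support = %d; no blocks callable",
                 n_samples, min_support))
    return(as_block_tbl(empty, cohort, min_support))
  }
  peaks <- normalize_peaks(peaks, genome)
  prof <- support_profile(peaks, genome)
  hit <- prof[prof$depth >= min_support, c("chrom", "start", "end")]
  blocks <- normalize_intervals(hit, genome)
  if (metrics) {
    blocks <- block_metrics(blocks, peaks, genome = genome, clip = clip)
  }
  as_block_tbl(blocks, cohort, min_support)
}

as_block_tbl <- function(blocks, cohort = NA_character_, min_support = NA_integer_) {
  attr(blocks, "cohort") <- cohort
  attr(blocks, "min_support") <- min_support
  blocks
}

#' Per-block occupancy metrics
#'
#' For each block: `n_positive` is the number of samples with at least 1 bp
#' of peak overlapping the block; `sum_peak_bp` sums the lengths of every
#' overlapping peak across positive samples (full peak length by default —
#' the length a peak contributes is not clipped to the block; set
#' `clip = TRUE` for in-block portions only); `sum_reads` sums the read
#' counts of those peaks (0 when read counts are absent). A peak overlapping
#' two blocks counts toward each.
#'
#' @param blocks Block tibble (intervals).
#' @param peaks Long peak tibble the blocks were called from.
#' @param genome Optional genome tibble.
#' @param clip Count only in-block peak bp (default `FALSE`).
#' @return The block tibble with metric columns filled.
#' @export
block_metrics <- function(blocks, peaks, genome = NULL, clip = FALSE) {
  check_interval_frame(blocks, "blocks")
  check_peaks(peaks, genome)
  base <- tibble(chrom = blocks$chrom, start = blocks$start, end = blocks$end)
  if (nrow(base) == 0) {
    base$n_positive <- integer()
    base$sum_peak_bp <- numeric()
    base$sum_reads <- numeric()
    return(as_block_tbl(base, attr(blocks, "cohort"), attr(blocks, "min_support")))
  }
  levels <- chrom_levels(dplyr::bind_rows(base, peaks[c("chrom", "start", "end")]),
                         genome)
  bgr <- ivl_to_gr(base, genome, levels)
  pgr <- ivl_to_gr(peaks, genome, levels)
  hits <- GenomicRanges::findOverlaps(bgr, pgr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  has_reads <- "reads" %in% names(peaks)
  peak_len <- if (clip) {
    GenomicRanges::width(IRanges::pintersect(bgr[qh], pgr[sh]))
  } else {
    GenomicRanges::width(pgr[sh])
  }
  ht <- tibble(
    block = qh,
    sample_id = peaks$sample_id[sh],
    len = as.numeric(peak_len),
    reads = if (has_reads) as.numeric(peaks$reads[sh]) else 0
  )
  agg <- ht %>%
    dplyr::group_by(.data$block) %>%
    dplyr::summarise(
      n_positive = dplyr::n_distinct(.data$sample_id),
      sum_peak_bp = sum(.data$len),
      sum_reads = sum(.data$reads),
      .groups = "drop"
    )
  base$n_positive <- 0L
  base$sum_peak_bp <- 0
  base$sum_reads <- 0
  base$n_positive[agg$block] <- agg$n_positive
  base$sum_peak_bp[agg$block] <- agg$sum_peak_bp
  base$sum_reads[agg$block] <- agg$sum_reads
  as_block_tbl(base, attr(blocks, "cohort"), attr(blocks, "min_support"))
}

#' Classify peak sharing across samples
#'
#' Each peak of each sample gets a sharing degree: the number of samples
#' (including its own) with at least 1 bp of overlap with it. Fractions are
#' computed over the pooled peak list of all samples, mirroring how the
#' fraction of "unique" peaks in a cohort is usually reported.
#'
#' @param peaks Long peak tibble.
#' @param n_samples Number of samples in the cohort; defaults to the number
#'   of distinct `sample_id` values present.
#' @param genome Optional genome tibble.
#' @return An object of class `hmc_sharing`: a list with the per-degree
#'   `histogram` tibble (`degree`, `n_peaks`, `fraction`), `n_samples`,
#'   `n_peaks`, `unique_fraction` and `shared_by_all_fraction`.
#' @export
classify_peak_sharing <- function(peaks, n_samples = NULL, genome = NULL) {
  check_peaks(peaks, genome)
  if (is.null(n_samples)) n_samples <- dplyr::n_distinct(peaks$sample_id)
  if (n_samples < 2) abort("peak sharing needs at least 2 samples")
  peaks <- normalize_peaks(peaks, genome)
  gr <- ivl_to_gr(peaks, genome)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  deg <- tibble(
    q = S4Vectors::queryHits(hits),
    sample_id = peaks$sample_id[S4Vectors::subjectHits(hits)]
  ) %>%
    dplyr::group_by(.data$q) %>%
    dplyr::summarise(degree = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop")
  degree <- integer(nrow(peaks))
  degree[deg$q] <- deg$degree
  n_total <- length(degree)
  hist <- tibble(degree = seq_len(n_samples)) %>%
    dplyr::left_join(
      tibble(degree = degree) %>% dplyr::count(.data$degree, name = "n_peaks"),
      by = "degree"
    ) %>%
    dplyr::mutate(
      n_peaks = dplyr::coalesce(.data$n_peaks, 0L),
      fraction = .data$n_peaks / n_total
    )
  structure(
    list(
      histogram = hist,
      n_samples = n_samples,
      n_peaks = nrow(peaks),
      unique_fraction = mean(degree == 1),
      shared_by_all_fraction = mean(degree == n_samples)
    ),
    class = "hmc_sharing"
  )
}

#' @export
print.hmc_sharing <- function(x, ...) {
  cat(sprintf(
    "Peak sharing across %d samples (%d peaks)\n  unique: %.1f%%  shared by all: %.1f%%\n",
    x$n_samples, x$n_peaks, 100 * x$unique_fraction,
    100 * x$shared_by_all_fraction
  ))
  print(x$histogram, ...)
  invisible(x)
}

#' Cohort-specific (developmental) blocks
#'
#' Partitions two cohorts' block sets into cohort-only blocks and shared
#' pairs. In `"block"` mode (default) a block is cohort-only iff it has zero
#' bp overlap with every block of the other cohort. In `"base"` mode the
#' other cohort's blocks are subtracted base-by-base and fragments of at
#' least `min_fragment` bp are kept (metric columns are dropped, since
#' fragments are no longer the called blocks).
#'
#' @param a,b Block tibbles (e.g. fetal and adult).
#' @param mode `"block"` or `"base"`.
#' @param min_fragment Minimum fragment length kept in `"base"` mode.
#' @param genome Optional genome tibble.
#' @return A list with `a_only`, `b_only` (block tibbles) and `shared`
#'   (a tibble of overlapping index pairs `a_index`, `b_index`).
#' @export
cohort_specific_blocks <- function(a, b, mode = c("block", "base"),
                                   min_fragment = 1L, genome = NULL) {
  mode <- match.arg(mode)
  check_intervals(a, genome, "a")
  check_intervals(b, genome, "b")
  levels <- chrom_levels(dplyr::bind_rows(a[c("chrom", "start", "end")],
                                          b[c("chrom", "start", "end")]),
                         genome)
  gra <- ivl_to_gr(a, genome, levels)
  grb <- ivl_to_gr(b, genome, levels)
  hits <- GenomicRanges::findOverlaps(gra, grb)
  shared <- tibble(a_index = S4Vectors::queryHits(hits),
                   b_index = S4Vectors::subjectHits(hits))
  if (mode == "block") {
    a_only <- a[setdiff(seq_len(nrow(a)), shared$a_index), , drop = FALSE]
    b_only <- b[setdiff(seq_len(nrow(b)), shared$b_index), , drop = FALSE]
  } else {
    a_only <- subtract_intervals(a, b, genome)
    b_only <- subtract_intervals(b, a, genome)
    a_only <- a_only[(a_only$end - a_only$start) >= min_fragment, , drop = FALSE]
    b_only <- b_only[(b_only$end - b_only$start) >= min_fragment, , drop = FALSE]
  }
  list(
    a_only = as_block_tbl(a_only, attr(a, "cohort"), attr(a, "min_support")),
    b_only = as_block_tbl(b_only, attr(b, "cohort"), attr(b, "min_support")),
    shared = shared
  )
}

#' Cross-tissue base-pair overlap of block sets
#'
#' Computes the bp of each set, their pairwise intersection, the percentage
#' of `b`'s bases covered by `a`, and (when a third set is given) the
#' three-way intersection.
#'
#' @param a,b Block/interval tibbles.
#' @param c Optional third interval tibble.
#' @param genome Optional genome tibble.
#' @return A one-row tibble: `bp_a`, `bp_b`, `bp_ab`, `pct_of_b_in_a`,
#'   `bp_abc` (`NA` without `c`).
#' @export
cross_tissue_overlap <- function(a, b, c = NULL, genome = NULL) {
  a <- normalize_intervals(a, genome)
  b <- normalize_intervals(b, genome)
  ab <- intersect_intervals(a, b, genome)
  bp_ab <- interval_bp(ab)
  bp_b <- interval_bp(b)
  bp_abc <- NA_real_
  if (!is.null(c)) {
    c <- normalize_intervals(c, genome)
    bp_abc <- interval_bp(intersect_intervals(ab, c, genome))
  }
  tibble(
    bp_a = interval_bp(a),
    bp_b = bp_b,
    bp_ab = bp_ab,
    pct_of_b_in_a = if (bp_b > 0) 100 * bp_ab / bp_b else NA_real_,
    bp_abc = bp_abc
  )
}

#' Read and write block tables
#'
#' Blocks are 6-column TSVs with a header: `chrom`, `start`, `end`,
#' `n_positive`, `sum_peak_bp`, `sum_reads` (genomic coordinates 0-based
#' half-open; the three metric columns describe 5hmC occupancy across the
#' cohort's samples).
#'
#' @param path File path.
#' @return `read_blocks()` returns a block tibble; `write_blocks()` returns
#'   `path` invisibly.
#' @export
read_blocks <- function(path) {
  if (!file.exists(path)) abort(paste0("block table not found: ", path))
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "i", end = "i", n_positive = "i",
    sum_peak_bp = "d", sum_reads = "d"
  ), progress = FALSE)
}

#' @rdname read_blocks
#' @param blocks Block tibble with metric columns.
#' @export
write_blocks <- function(blocks, path) {
  need <- c("chrom", "start", "end", "n_positive", "sum_peak_bp", "sum_reads")
  if (!all(need %in% names(blocks))) {
    abort("blocks must have columns chrom, start, end, n_positive, sum_peak_bp, sum_reads")
  }
  readr::write_tsv(blocks[need], path)
  invisible(path)
}
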