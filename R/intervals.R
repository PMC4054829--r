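# Interval tables are plain tibbles with columns chrom/start/end (BED
# convention: 0-based, half-open) plus any number of extra columns. The
# algebra below is backed by IRanges/GenomicRanges; strand is ignored
# throughout.

empty_intervals <- function() {
  tibble(chrom = character(), start = integer(), end = integer())
}

check_interval_frame <- function(x, arg = "x") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(paste0("`", arg, "` must have columns chrom, start and end"))
  }
  invisible(x)
}

# Validate coordinates against a genome declaration (when given) and basic
# interval sanity. Errors name the offending chromosome/coordinates.
check_intervals <- function(x, genome = NULL, arg = "x") {
  check_interval_frame(x, arg)
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end)
  if (length(bad)) {
    i <- bad[1]
    abort(sprintf(
      "invalid interval in `%s`: %s:%s-%s (need 0 <= start < end)",
      arg, x$chrom[i], format(x$start[i], scientific = FALSE),
      format(x$end[i], scientific = FALSE)
    ))
  }
  if (!is.null(genome)) {
    check_genome(genome)
    unknown <- setdiff(unique(x$chrom), genome$chrom)
    if (length(unknown)) {
      abort(paste0("interval chromosome(s) not in genome: ",
                   paste(unknown, collapse = ", ")))
    }
    sizes <- genome$size[match(x$chrom, genome$chrom)]
    over <- which(x$end > sizes)
    if (length(over)) {
      i <- over[1]
      abort(sprintf(
        "interval out of bounds: %s:%s-%s exceeds chromosome length %s",
        x$chrom[i], format(x$start[i], scientific = FALSE),
        format(x$end[i], scientific = FALSE),
        format(sizes[i], scientific = FALSE)
      ))
    }
  }
  invisible(x)
}

chrom_levels <- function(x, genome = NULL) {
  if (!is.null(genome)) genome$chrom else sort(unique(as.character(x$chrom)))
}

# tibble (0-based half-open) -> GRanges (1-based closed)
ivl_to_gr <- function(x, genome = NULL, levels = NULL) {
  if (is.null(levels)) levels <- chrom_levels(x, genome)
  seqinfo <- if (!is.null(genome)) {
    GenomeInfoDb::Seqinfo(genome$chrom, genome$size)
  } else {
    GenomeInfoDb::Seqinfo(levels)
  }
  if (nrow(x) == 0) {
    return(GenomicRanges::GRanges(seqinfo = seqinfo))
  }
  GenomicRanges::GRanges(
    seqnames = factor(as.character(x$chrom), levels = levels),
    ranges = IRanges::IRanges(start = as.integer(x$start) + 1L,
                              end = as.integer(x$end)),
    seqinfo = seqinfo
  )
}

# GRanges -> tibble (0-based half-open), sorted by (chrom, start)
gr_to_ivl <- function(gr) {
  if (length(gr) == 0) return(empty_intervals())
  gr <- GenomicRanges::sort(gr)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Normalize a set of genomic intervals
#'
#' Sorts intervals by (chrom, start) and coalesces overlapping *and*
#' bookended intervals (an interval ending exactly where the next one starts)
#' into maximal disjoint runs. Normalization is idempotent, and every other
#' interval operation in the package assumes (or enforces) normalized input.
#'
#' @param x Interval tibble with columns `chrom`, `start`, `end`
#'   (0-based, half-open). Extra columns are dropped.
#' @param genome Optional genome tibble; when supplied, intervals outside the
#'   declared chromosomes/bounds raise an error.
#'
#' @return A normalized interval tibble.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(100, 150), end = c(200, 250))
#' normalize_intervals(x)
#' @export
normalize_intervals <- function(x, genome = NULL) {
  check_intervals(x, genome)
  if (nrow(x) == 0) return(empty_intervals())
  gr_to_ivl(GenomicRanges::reduce(ivl_to_gr(x, genome)))
}

#' Interval-set intersection and subtraction
#'
#' `intersect_intervals()` returns exactly the bases present in both sets;
#' `subtract_intervals()` the bases in `a` that are not in `b`. Both operands
#' are normalized internally, so results are normalized interval tibbles.
#'
#' @param a,b Interval tibbles.
#' @param genome Optional genome tibble for bounds checking.
#' @return A normalized interval tibble.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' intersect_intervals(a, b)
#' subtract_intervals(a, b)
#' @export
intersect_intervals <- function(a, b, genome = NULL) {
  check_intervals(a, genome, "a")
  check_intervals(b, genome, "b")
  levels <- if (!is.null(genome)) genome$chrom else {
    sort(unique(c(as.character(a$chrom), as.character(b$chrom))))
  }
  gra <- ivl_to_gr(a, genome, levels)
  grb <- ivl_to_gr(b, genome, levels)
  gr_to_ivl(GenomicRanges::intersect(gra, grb, ignore.strand = TRUE))
}

#' @rdname intersect_intervals
#' @export
subtract_intervals <- function(a, b, genome = NULL) {
  check_intervals(a, genome, "a")
  check_intervals(b, genome, "b")
  levels <- if (!is.null(genome)) genome$chrom else {
    sort(unique(c(as.character(a$chrom), as.character(b$chrom))))
  }
  gra <- ivl_to_gr(a, genome, levels)
  grb <- ivl_to_gr(b, genome, levels)
  gr_to_ivl(GenomicRanges::setdiff(gra, grb, ignore.strand = TRUE))
}

#' Total length of an interval set in bp
#'
#' Assumes (and enforces) a normalized input would give the same answer only
#' for disjoint intervals; overlapping rows are counted per-row, so normalize
#' first if rows may overlap.
#'
#' @param x Interval tibble.
#' @return Total bp (numeric scalar).
#' @export
interval_bp <- function(x) {
  check_interval_frame(x)
  if (nrow(x) == 0) return(0)
  sum(as.numeric(x$end) - as.numeric(x$start))
}

#' Per-base sample-support profile
#'
#' Given one normalized interval set per sample, returns the maximal runs of
#' constant per-base support (the number of samples covering each base).
#' Runs with zero support are omitted, so the returned runs tile exactly the
#' union of the inputs. This profile is the substrate for consensus block
#' calling.
#'
#' @param peak_sets A list of interval tibbles (one per sample), or a single
#'   tibble with a `sample_id` column.
#' @param genome Optional genome tibble for bounds checking.
#' @return A tibble with columns `chrom`, `start`, `end`, `depth`.
#' @examples
#' s1 <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' s2 <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' support_profile(list(s1, s2))
#' @export
support_profile <- function(peak_sets, genome = NULL) {
  if (is.data.frame(peak_sets)) {
    check_interval_frame(peak_sets)
    if (!"sample_id" %in% names(peak_sets)) {
      abort("a single-tibble `peak_sets` needs a `sample_id` column")
    }
    peak_sets <- split(peak_sets[c("chrom", "start", "end")],
                       peak_sets$sample_id)
  }
  peak_sets <- lapply(peak_sets, normalize_intervals, genome = genome)
  nonempty <- peak_sets[vapply(peak_sets, nrow, 0L) > 0]
  if (length(nonempty) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  depth = integer()))
  }
  all_ivl <- dplyr::bind_rows(nonempty)
  gr <- ivl_to_gr(all_ivl, genome)
  cvg <- GenomicRanges::coverage(gr)
  runs <- lapply(names(cvg), function(chr) {
    r <- cvg[[chr]]
    if (length(r) == 0) return(NULL)
    len <- S4Vectors::runLength(r)
    val <- S4Vectors::runValue(r)
    ends <- cumsum(as.numeric(len))
    starts <- ends - as.numeric(len)
    keep <- val > 0
    if (!any(keep)) return(NULL)
    tibble(chrom = chr, start = starts[keep], end = ends[keep],
           depth = as.integer(val[keep]))
  })
  out <- dplyr::bind_rows(runs)
  lv <- chrom_levels(out, genome)
  dplyr::arrange(out, factor(.data$chrom, levels = lv), .data$start)
}

#' Read and write BED files
#'
#' Reads BED3/BED5 (tab-separated, 0-based half-open). When five or more
#' columns are present, column 5 is kept as `score` (hmcblocks uses it to
#' carry per-peak read counts). Malformed lines raise an error naming the
#' line number; `start >= end` is rejected.
#'
#' @param path File path.
#' @param genome Optional genome tibble; intervals are bounds-checked when
#'   supplied.
#' @return `read_bed()` returns an interval tibble (with a `score` column for
#'   BED5 input); `write_bed()` returns `path` invisibly.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) return(empty_intervals())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields",
                  idx[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: non-numeric coordinates", idx[bad[1]]))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: start >= end (or negative start)",
                  idx[bad[1]]))
  }
  out <- tibble(chrom = chrom, start = as.integer(start), end = as.integer(end))
  if (all(nf >= 5)) {
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    bad <- which(is.na(score))
    if (length(bad)) {
      abort(sprintf("malformed BED line %d: non-numeric score", idx[bad[1]]))
    }
    out$score <- score
  }
  check_intervals(out, genome, "bed")
  out
}

#' @rdname read_bed
#' @param x Interval tibble; a `score` column, when present, is written as
#'   BED5 (with `.` in the name field).
#' @export
write_bed <- function(x, path) {
  check_interval_frame(x)
  if ("score" %in% names(x)) {
    out <- data.frame(chrom = x$chrom,
                      start = format(x$start, scientific = FALSE, trim = TRUE),
                      end = format(x$end, scientific = FALSE, trim = TRUE),
                      name = ".",
                      score = format(x$score, scientific = FALSE, trim = TRUE))
  } else {
    out <- data.frame(chrom = x$chrom,
                      start = format(x$start, scientific = FALSE, trim = TRUE),
                      end = format(x$end, scientific = FALSE, trim = TRUE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
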