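# Brute-force per-base oracles, deliberately independent of the package's
# GenomicRanges-backed implementation: a chromosome is a logical (or
# integer) vector with one element per base.

toy_genome <- function(n_chroms = 3, min_len = 500, max_len = 2000) {
  hmc_genome(paste0("chr", seq_len(n_chroms)),
             sample(seq(min_len, max_len), n_chroms, replace = TRUE))
}

random_intervals <- function(genome, n = 10, max_len = 200) {
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  len <- pmin(len, genome$size[ci])
  start <- floor(runif(n) * (genome$size[ci] - len + 1))
  tibble::tibble(chrom = genome$chrom[ci], start = start, end = start + len)
}

# interval tibble -> list of per-chromosome base masks
ivl_mask <- function(x, genome) {
  masks <- lapply(stats::setNames(genome$size, genome$chrom), function(s) {
    rep(FALSE, s)
  })
  for (i in seq_len(nrow(x))) {
    m <- masks[[x$chrom[i]]]
    m[seq(x$start[i] + 1, x$end[i])] <- TRUE
    masks[[x$chrom[i]]] <- m
  }
  masks
}

# base masks -> normalized interval tibble
mask_ivl <- function(masks) {
  rows <- lapply(names(masks), function(chr) {
    m <- masks[[chr]]
    if (!any(m)) return(NULL)
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    tibble::tibble(chrom = chr, start = starts[keep], end = ends[keep])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  out
}

mask_op <- function(a, b, op) {
  out <- a
  for (chr in names(a)) out[[chr]] <- op(a[[chr]], b[[chr]])
  out
}

# per-base support counts across a list of interval sets
support_mask <- function(sets, genome) {
  counts <- lapply(stats::setNames(genome$size, genome$chrom), function(s) {
    integer(s)
  })
  for (s in sets) {
    m <- ivl_mask(s, genome)
    for (chr in names(counts)) counts[[chr]] <- counts[[chr]] + m[[chr]]
  }
  counts
}

# support counts -> runs tibble (depth > 0)
support_runs <- function(counts) {
  rows <- lapply(names(counts), function(chr) {
    v <- counts[[chr]]
    if (!any(v > 0)) return(NULL)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values > 0
    tibble::tibble(chrom = chr, start = starts[keep], end = ends[keep],
                   depth = as.integer(r$values[keep]))
  })
  dplyr::bind_rows(rows)
}

# support counts at threshold -> block intervals
blocks_from_counts <- function(counts, min_support) {
  mask_ivl(lapply(counts, function(v) v >= min_support))
}

expect_same_intervals <- function(x, y) {
  expect_equal(
    as.data.frame(dplyr::arrange(x[c("chrom", "start", "end")],
                                 chrom, start)),
    as.data.frame(dplyr::arrange(y[c("chrom", "start", "end")],
                                 chrom, start)),
    ignore_attr = TRUE
  )
}
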