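toy_peaks <- function(...) {
  sets <- list(...)
  dplyr::bind_rows(lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    s$sample_id <- paste0("s", i)
    s
  }))
}

test_that("call_blocks finds the >=2-support runs", {
  g <- hmc_genome("chr1", 1000)
  pk <- toy_peaks(
    tibble::tibble(chrom = "chr1", start = 100, end = 200),
    tibble::tibble(chrom = "chr1", start = 150, end = 250)
  )
  b <- call_blocks(pk, 2, g)
  expect_equal(b[c("chrom", "start", "end")],
               tibble::tibble(chrom = "chr1", start = 150L, end = 200L),
               ignore_attr = TRUE)
  # a single sample cannot support a 2-sample block
  single <- toy_peaks(tibble::tibble(chrom = "chr1", start = 0, end = 100))
  expect_warning(b1 <- call_blocks(single, 2, g), "min_support")
  expect_equal(nrow(b1), 0)
  # staggered example: runs where support >= 2
  pk3 <- toy_peaks(
    tibble::tibble(chrom = "chr1", start = c(0, 300), end = c(100, 400)),
    tibble::tibble(chrom = "chr1", start = 50, end = 350),
    tibble::tibble(chrom = "chr1", start = 80, end = 120)
  )
  b3 <- call_blocks(pk3, 2, g)
  expect_equal(b3$start, c(50L, 300L))
  expect_equal(b3$end, c(120L, 350L))
})

test_that("mixed cohorts are rejected", {
  pk <- tibble::tibble(chrom = "chr1", start = c(0, 50), end = c(10, 60),
                       sample_id = c("a", "b"), cohort = c("fetal", "adult"))
  expect_error(call_blocks(pk, 2), "mix cohorts")
})

test_that("block metrics sum full peak lengths and reads", {
  g <- hmc_genome("chr1", 1000)
  pk <- toy_peaks(
    tibble::tibble(chrom = "chr1", start = 100, end = 200, reads = 40),
    tibble::tibble(chrom = "chr1", start = 150, end = 250, reads = 60)
  )
  b <- call_blocks(pk, 2, g)
  expect_equal(b$n_positive, 2L)
  expect_equal(b$sum_peak_bp, 200)  # full peak lengths, not in-block bp
  expect_equal(b$sum_reads, 100)
  clipped <- call_blocks(pk, 2, g, clip = TRUE)
  expect_equal(clipped$sum_peak_bp, 100)  # 50 in-block bp from each peak
  # two minimally-overlapping 500 bp peaks
  pk2 <- toy_peaks(
    tibble::tibble(chrom = "chr1", start = 0, end = 500),
    tibble::tibble(chrom = "chr1", start = 499, end = 999)
  )
  b2 <- call_blocks(pk2, 2, g)
  expect_equal(b2$sum_peak_bp, 1000)
})

test_that("block calling and metrics match brute-force oracles", {
  withr::local_seed(1203)
  for (i in 1:30) {
    g <- toy_genome()
    n_samples <- sample(3:5, 1)
    sets <- lapply(seq_len(n_samples), function(j) {
      normalize_intervals(random_intervals(g, n = sample(2:8, 1)), g)
    })
    pk <- dplyr::bind_rows(lapply(seq_along(sets), function(j) {
      s <- sets[[j]]
      s$sample_id <- paste0("s", j)
      s$reads <- sample(10:100, nrow(s), replace = TRUE)
      s
    }))
    min_support <- sample(2:3, 1)
    b <- call_blocks(pk, min_support, g)
    oracle <- blocks_from_counts(support_mask(sets, g), min_support)
    expect_same_intervals(b, oracle)
    # metrics by exhaustive pairwise overlap scan
    for (r in seq_len(nrow(b))) {
      ov <- pk$chrom == b$chrom[r] & pk$start < b$end[r] & pk$end > b$start[r]
      expect_equal(b$n_positive[r], length(unique(pk$sample_id[ov])))
      expect_equal(b$sum_peak_bp[r], sum(pk$end[ov] - pk$start[ov]))
      expect_equal(b$sum_reads[r], sum(pk$reads[ov]))
    }
    # monotone shrinkage: higher support never adds block bases
    b_hi <- suppressWarnings(call_blocks(pk, min_support + 1, g))
    expect_equal(interval_bp(subtract_intervals(b_hi, b, g)), 0)
    # blocks live inside the union of all peaks
    expect_equal(interval_bp(subtract_intervals(
      b, normalize_intervals(pk, g), g)), 0)
  }
})

test_that("peak sharing degrees match the quadratic overlap oracle", {
  g <- hmc_genome("chr1", 1000)
  # identical peaks in 2 samples: all shared
  ident <- toy_peaks(
    tibble::tibble(chrom = "chr1", start = 100, end = 200),
    tibble::tibble(chrom = "chr1", start = 100, end = 200)
  )
  sh <- classify_peak_sharing(ident, genome = g)
  expect_equal(sh$unique_fraction, 0)
  expect_equal(sh$shared_by_all_fraction, 1)
  # disjoint peaks: all unique
  disj <- toy_peaks(
    tibble::tibble(chrom = "chr1", start = 100, end = 200),
    tibble::tibble(chrom = "chr1", start = 300, end = 400)
  )
  sh2 <- classify_peak_sharing(disj, genome = g)
  expect_equal(sh2$unique_fraction, 1)
  expect_equal(sh2$shared_by_all_fraction, 0)
  # random sets vs brute force
  withr::local_seed(77)
  for (i in 1:15) {
    gg <- toy_genome()
    n_samples <- sample(3:5, 1)
    pk <- dplyr::bind_rows(lapply(seq_len(n_samples), function(j) {
      s <- normalize_intervals(random_intervals(gg, sample(2:6, 1)), gg)
      s$sample_id <- paste0("s", j)
      s
    }))
    sh <- classify_peak_sharing(pk, genome = gg)
    deg <- vapply(seq_len(nrow(pk)), function(r) {
      ov <- pk$chrom == pk$chrom[r] & pk$start < pk$end[r] &
        pk$end > pk$start[r]
      length(unique(pk$sample_id[ov]))
    }, 0L)
    oracle_hist <- table(factor(deg, levels = seq_len(n_samples)))
    expect_equal(sh$histogram$n_peaks, as.integer(oracle_hist))
    expect_equal(sum(sh$histogram$fraction), 1)
    expect_equal(sh$unique_fraction, mean(deg == 1))
    expect_equal(sh$shared_by_all_fraction, mean(deg == n_samples))
  }
})

test_that("cohort-specific blocks partition by zero-overlap", {
  g <- hmc_genome("chr1", 1000)
  A <- tibble::tibble(chrom = "chr1", start = 100, end = 200,
                      n_positive = 2L, sum_peak_bp = 0, sum_reads = 0)
  B <- tibble::tibble(chrom = "chr1", start = 150, end = 250,
                      n_positive = 2L, sum_peak_bp = 0, sum_reads = 0)
  sp <- cohort_specific_blocks(A, B, genome = g)
  expect_equal(nrow(sp$a_only), 0)
  expect_equal(sp$shared, tibble::tibble(a_index = 1L, b_index = 1L))
  B2 <- dplyr::mutate(B, start = 300, end = 400)
  sp2 <- cohort_specific_blocks(A, B2, genome = g)
  expect_equal(sp2$a_only, A)
  expect_equal(sp2$b_only, B2)
  # random partition check: a_only + a-overlapping = all of a
  withr::local_seed(31)
  for (i in 1:10) {
    gg <- toy_genome()
    a <- normalize_intervals(random_intervals(gg, 8), gg)
    b <- normalize_intervals(random_intervals(gg, 8), gg)
    sp <- cohort_specific_blocks(a, b, genome = gg)
    ov <- vapply(seq_len(nrow(a)), function(r) {
      any(b$chrom == a$chrom[r] & b$start < a$end[r] & b$end > a$start[r])
    }, TRUE)
    expect_equal(nrow(sp$a_only), sum(!ov))
    expect_equal(nrow(sp$a_only) + length(unique(sp$shared$a_index)), nrow(a))
  }
  # base-level variant subtracts and filters fragments
  spb <- cohort_specific_blocks(A, B, mode = "base", min_fragment = 30,
                                genome = g)
  expect_equal(spb$a_only[c("chrom", "start", "end")],
               tibble::tibble(chrom = "chr1", start = 100L, end = 150L))
})

test_that("cross-tissue overlap reports bp and percentages", {
  g <- hmc_genome("chr1", 2000)
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  b <- tibble::tibble(chrom = "chr1", start = 500, end = 1500)
  cc <- tibble::tibble(chrom = "chr1", start = 900, end = 1100)
  ov <- cross_tissue_overlap(a, b, cc, g)
  expect_equal(ov$bp_ab, 500)
  expect_equal(ov$bp_abc, 100)
  expect_equal(ov$pct_of_b_in_a, 50)
  expect_equal(cross_tissue_overlap(a, a, genome = g)$pct_of_b_in_a, 100)
  disj <- tibble::tibble(chrom = "chr1", start = 1500, end = 1600)
  expect_equal(cross_tissue_overlap(a, disj, genome = g)$bp_ab, 0)
  expect_equal(cross_tissue_overlap(a, disj, genome = g)$pct_of_b_in_a, 0)
})

test_that("block tables round-trip through TSV", {
  g <- hmc_genome("chr1", 1000)
  pk <- toy_peaks(
    tibble::tibble(chrom = "chr1", start = c(100, 400), end = c(200, 500),
                   reads = c(10, 20)),
    tibble::tibble(chrom = "chr1", start = 150, end = 450, reads = 30)
  )
  b <- call_blocks(pk, 2, g)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_blocks(b, path)
  back <- read_blocks(path)
  expect_equal(as.data.frame(back), as.data.frame(b), ignore_attr = TRUE)
})
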