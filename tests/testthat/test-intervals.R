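test_that("normalize_intervals merges overlapping and bookended intervals", {
  g <- hmc_genome("chr1", 1000)
  x <- tibble::tibble(chrom = "chr1", start = c(100, 150), end = c(200, 250))
  expect_equal(normalize_intervals(x, g),
               tibble::tibble(chrom = "chr1", start = 100L, end = 250L))
  # bookended intervals coalesce: blocks are defined by base support
  x2 <- tibble::tibble(chrom = "chr1", start = c(0, 10), end = c(10, 20))
  expect_equal(normalize_intervals(x2, g),
               tibble::tibble(chrom = "chr1", start = 0L, end = 20L))
  # empty identity and idempotence
  expect_equal(nrow(normalize_intervals(empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer()), g)), 0)
  norm <- normalize_intervals(x, g)
  expect_equal(normalize_intervals(norm, g), norm)
})

test_that("intervals outside the declared genome raise named errors", {
  g <- hmc_genome("chr1", 1000)
  expect_error(
    normalize_intervals(tibble::tibble(chrom = "chr2", start = 0, end = 10), g),
    "chr2"
  )
  expect_error(
    normalize_intervals(tibble::tibble(chrom = "chr1", start = 900, end = 1100), g),
    "out of bounds"
  )
  expect_error(
    normalize_intervals(tibble::tibble(chrom = "chr1", start = 50, end = 50), g),
    "start < end"
  )
})

test_that("intersect and subtract match their simple examples", {
  g <- hmc_genome(c("chr1", "chr2"), c(1000, 1000))
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
  expect_equal(intersect_intervals(a, b, g),
               tibble::tibble(chrom = "chr1", start = 50L, end = 100L))
  expect_equal(intersect_intervals(a, a, g),
               tibble::tibble(chrom = "chr1", start = 0L, end = 100L))
  expect_equal(nrow(intersect_intervals(
    a, tibble::tibble(chrom = "chr2", start = 0, end = 100), g)), 0)
  expect_equal(subtract_intervals(a, b, g),
               tibble::tibble(chrom = "chr1", start = 0L, end = 50L))
  expect_equal(subtract_intervals(a, a[0, ], g),
               tibble::tibble(chrom = "chr1", start = 0L, end = 100L))
  expect_equal(
    subtract_intervals(a, tibble::tibble(chrom = "chr1",
                                         start = c(20, 60), end = c(30, 70)), g),
    tibble::tibble(chrom = "chr1", start = c(0L, 30L, 70L),
                   end = c(20L, 60L, 100L))
  )
  expect_equal(nrow(subtract_intervals(a, a, g)), 0)
})

test_that("support_profile reports maximal constant-support runs", {
  g <- hmc_genome("chr1", 1000)
  s1 <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  s2 <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
  prof <- support_profile(list(s1, s2), g)
  expect_equal(prof$depth, c(1L, 2L, 1L))
  expect_equal(prof$start, c(0, 50, 100))
  expect_equal(prof$end, c(50, 100, 150))
  # one empty set contributes nothing
  prof2 <- support_profile(list(s1, s1[0, ], s2), g)
  expect_equal(prof, prof2)
})

test_that("interval algebra agrees with a per-base membership oracle", {
  withr::local_seed(421)
  for (i in 1:40) {
    g <- toy_genome()
    a <- random_intervals(g, n = sample(0:12, 1))
    b <- random_intervals(g, n = sample(1:12, 1))
    ma <- ivl_mask(a, g)
    mb <- ivl_mask(b, g)
    expect_same_intervals(normalize_intervals(a, g), mask_ivl(ma))
    expect_same_intervals(intersect_intervals(a, b, g),
                          mask_ivl(mask_op(ma, mb, `&`)))
    expect_same_intervals(subtract_intervals(a, b, g),
                          mask_ivl(mask_op(ma, mb, function(x, y) x & !y)))
    # conservation: bases of a split exactly into (a and b) + (a not b)
    expect_equal(
      interval_bp(intersect_intervals(a, b, g)) +
        interval_bp(subtract_intervals(a, b, g)),
      interval_bp(normalize_intervals(a, g))
    )
  }
})

test_that("support_profile matches a per-base counting oracle", {
  withr::local_seed(99)
  for (i in 1:20) {
    g <- toy_genome()
    sets <- lapply(seq_len(sample(2:4, 1)), function(j) {
      normalize_intervals(random_intervals(g, n = sample(1:8, 1)), g)
    })
    prof <- support_profile(sets, g)
    oracle <- support_runs(support_mask(sets, g))
    expect_equal(as.data.frame(prof), as.data.frame(oracle),
                 ignore_attr = TRUE)
    # depth-weighted run lengths account for every sample base
    expect_equal(sum((prof$end - prof$start) * prof$depth),
                 sum(vapply(sets, interval_bp, 0)))
  }
})

test_that("BED round-trips preserve intervals and scores", {
  g <- hmc_genome("chr1", 10000)
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", path)
  expect_equal(read_bed(path, g),
               tibble::tibble(chrom = "chr1", start = 100L, end = 200L))
  x <- normalize_intervals(random_intervals(g, 5), g)
  write_bed(x, path)
  expect_equal(read_bed(path, g), x)
  scored <- tibble::tibble(chrom = "chr1", start = 10, end = 50, score = 40)
  write_bed(scored, path)
  back <- read_bed(path, g)
  expect_equal(back$score, 40)
})

test_that("malformed BED lines are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\tfoo\t200"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t0\t100", "chr1\t300\t200"), path)
  expect_error(read_bed(path), "line 2")
  writeLines("chr1\t100", path)
  expect_error(read_bed(path), "fewer than 3 fields")
})
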