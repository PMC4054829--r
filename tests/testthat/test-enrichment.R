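test_that("analytic fold follows the ratio-of-proportions formula", {
  g <- hmc_genome("chr1", 1000)
  blocks <- tibble::tibble(chrom = "chr1", start = c(50, 500),
                           end = c(150, 600))
  feature <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  e <- tidy(analytic_enrichment(blocks, feature, g, name = "cgi"))
  # 50 of 200 block bp inside a 10% feature -> (50/200)/0.1
  expect_equal(e$fold, 2.5)
  expect_equal(e$observed_bp, 50)
  expect_equal(e$expected_bp, 20)
  # whole genome as the feature forces fold 1
  whole <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  expect_equal(tidy(analytic_enrichment(blocks, whole, g))$fold, 1)
  # disjoint blocks and feature
  far <- tibble::tibble(chrom = "chr1", start = 900, end = 950)
  expect_equal(tidy(analytic_enrichment(far, feature, g))$fold, 0)
  # empty inputs are named in errors
  expect_error(analytic_enrichment(blocks[0, ], feature, g), "block")
  expect_error(analytic_enrichment(blocks, feature[0, ], g, name = "cgi"),
               "cgi")
})

test_that("permutation enrichment is seeded, calibrated and sane on edge cases", {
  g <- hmc_genome(c("chr1", "chr2"), c(5000, 3000))
  blocks <- random_placement(rep(100, 20), g, seed = 5)
  feature <- tibble::tibble(chrom = c("chr1", "chr2"),
                            start = c(0, 1000), end = c(1000, 1500))
  p1 <- permutation_enrichment(blocks, feature, g, n_perm = 200, seed = 9)
  p2 <- permutation_enrichment(blocks, feature, g, n_perm = 200, seed = 9)
  expect_identical(tidy(p1), tidy(p2))
  # whole genome: every permutation overlaps fully -> fold 1, p 1
  whole <- tibble::tibble(chrom = c("chr1", "chr2"), start = 0,
                          end = c(5000, 3000))
  pw <- tidy(permutation_enrichment(blocks, whole, g, n_perm = 100, seed = 1))
  expect_equal(pw$fold, 1)
  expect_equal(pw$null_p, 1)
  # permutation fold approaches the analytic fold (analytic as oracle)
  a <- tidy(analytic_enrichment(blocks, feature, g))
  pr <- tidy(permutation_enrichment(blocks, feature, g, n_perm = 1000,
                                    seed = 3))
  se_fold <- pr$observed_bp * (pr$perm_sd_bp / sqrt(pr$n_perm)) /
    pr$perm_mean_bp^2
  expect_lt(abs(pr$fold - a$fold), 3 * se_fold + 1e-9)
  expect_error(permutation_enrichment(blocks, feature, g, n_perm = 50),
               "at least 100")
  # an interval longer than every chromosome cannot be placed
  expect_error(random_placement(6000, g, seed = 1),
               "longer than every chromosome")
  # a placement constrained to the chromosomes it fits on
  pl <- random_placement(rep(4000, 50), g, seed = 2)
  expect_true(all(pl$chrom == "chr1"))
  expect_true(all(pl$end <= 5000))
})

test_that("chromosome representation folds are exact on constructed cases", {
  g <- hmc_genome(c("chr1", "chr2"), c(1000, 1000))
  all_chr1 <- tibble::tibble(chrom = "chr1", start = 0, end = 500)
  cr <- chromosome_representation(all_chr1, g)
  expect_equal(cr$fold, c(2, 0))
  # blocks spread proportionally to length -> all folds 1
  prop <- tibble::tibble(chrom = c("chr1", "chr2"), start = 0, end = 100)
  expect_equal(chromosome_representation(prop, g)$fold, c(1, 1))
  # planted 2x density bias on chr1 is recovered
  g2 <- hmc_genome(c("chr1", "chr2"), c(50000, 50000))
  withr::local_seed(8)
  n1 <- 400; n2 <- 200
  s1 <- floor(runif(n1) * (50000 - 50))
  s2 <- floor(runif(n2) * (50000 - 50))
  biased <- normalize_intervals(tibble::tibble(
    chrom = rep(c("chr1", "chr2"), c(n1, n2)),
    start = c(s1, s2), end = c(s1, s2) + 50), g2)
  cr2 <- chromosome_representation(biased, g2)
  expect_gt(cr2$fold[1], 1.15)
  expect_lt(cr2$fold[2], 0.85)
  expect_equal(cr2$fold[1] / cr2$fold[2], 2, tolerance = 0.25)
})

test_that("expression-class enrichment uses gene bodies as reference space", {
  g <- hmc_genome("chr1", 10000)
  bodies <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    chrom = "chr1", start = c(0, 2000, 4000), end = c(1000, 3000, 5000)
  )
  classes <- tibble::tibble(gene_id = c("a", "b", "c"),
                            class = c("low", "intermediate", "high"))
  # blocks only in the "high" body, classes of equal bp -> fold 3, others 0
  blocks <- tibble::tibble(chrom = "chr1", start = 4100, end = 4400)
  e <- tidy(expression_class_enrichment(blocks, classes, bodies, g))
  expect_equal(e$fold[e$feature == "high"], 3)
  expect_equal(e$fold[e$feature == "low"], 0)
  # all genes one class -> fold 1
  one <- dplyr::mutate(classes, class = "all")
  expect_equal(tidy(expression_class_enrichment(blocks, one, bodies, g))$fold, 1)
  # weighted mean of folds over any partition of the reference space is 1
  withr::local_seed(44)
  for (i in 1:10) {
    blk <- random_placement(rep(150, 8), g)
    blk <- normalize_intervals(blk, g)
    cls <- tibble::tibble(gene_id = c("a", "b", "c"),
                          class = sample(c("x", "y"), 3, replace = TRUE))
    if (length(unique(cls$class)) < 2) next
    res <- tidy(expression_class_enrichment(blk, cls, bodies, g))
    if (sum(res$observed_bp) == 0) next
    expect_equal(sum(res$fold * res$feature_fraction), 1, tolerance = 1e-9)
  }
})

test_that("folds are invariant under coordinate scaling", {
  g <- hmc_genome(c("chr1", "chr2"), c(2000, 1000))
  blocks <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(100, 200),
                           end = c(300, 260))
  feature <- tibble::tibble(chrom = "chr1", start = 0, end = 500)
  f1 <- tidy(analytic_enrichment(blocks, feature, g))$fold
  k <- 7
  g2 <- hmc_genome(g$chrom, g$size * k)
  f2 <- tidy(analytic_enrichment(
    dplyr::mutate(blocks, start = start * k, end = end * k),
    dplyr::mutate(feature, start = start * k, end = end * k), g2))$fold
  expect_equal(f1, f2)
})

test_that("developmental group enrichment keeps only groups I-V", {
  g <- hmc_genome("chr1", 10000)
  bodies <- tibble::tibble(
    gene_id = letters[1:6], chrom = "chr1",
    start = seq(0, 5000, by = 1000), end = seq(500, 5500, by = 1000)
  )
  groups <- tibble::tibble(gene_id = letters[1:6],
                           group = c("I", "II", "III", "IV", "V",
                                     "unassigned"))
  blocks <- tibble::tibble(chrom = "chr1", start = 100, end = 300)
  e <- tidy(developmental_group_enrichment(blocks, groups, bodies, g))
  expect_setequal(e$feature, c("I", "II", "III", "IV", "V"))
  expect_equal(e$fold[e$feature == "I"], 5)  # all block bp in 1/5 of bodies
})

test_that("cgi shores flank islands without covering them", {
  g <- hmc_genome("chr1", 20000)
  cgi <- tibble::tibble(chrom = "chr1", start = c(5000, 6500), end = c(5600, 7000))
  sh <- cgi_shores(cgi, g, flank = 2000)
  expect_equal(interval_bp(intersect_intervals(sh, cgi, g)), 0)
  # shores stay within 2 kb of an island
  grown <- tibble::tibble(chrom = "chr1", start = 3000, end = 9000)
  expect_equal(interval_bp(subtract_intervals(sh, grown, g)), 0)
  # island at the chromosome edge is clipped
  edge <- tibble::tibble(chrom = "chr1", start = 0, end = 500)
  she <- cgi_shores(edge, g, flank = 2000)
  expect_equal(she, tibble::tibble(chrom = "chr1", start = 500L, end = 2500L))
})
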