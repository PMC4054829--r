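test_that("regulatory domains follow the basal-plus-extension rule", {
  g <- hmc_genome("chr1", 1e7)
  lone <- tibble::tibble(gene_id = "a", chrom = "chr1", strand = "+",
                         tss = 2e6, start = 2e6, end = 2.01e6)
  d <- build_regulatory_domains(lone, g)
  expect_equal(d$basal_start, 1995000)
  expect_equal(d$basal_end, 2001000)
  expect_equal(d$ext_start, 995000)
  expect_equal(d$ext_end, 3001000)
  # two genes on a 300 kb chromosome: hand-derived extension limits
  g2 <- hmc_genome("chr1", 3e5)
  two <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                        strand = "+", tss = c(1e5, 2e5),
                        start = c(1e5, 2e5), end = c(1.05e5, 2.05e5))
  d2 <- build_regulatory_domains(two, g2)
  expect_equal(d2$ext_start, c(0, 101000))
  expect_equal(d2$ext_end, c(195000, 300000))
  # minus strand mirrors the basal orientation
  minus <- dplyr::mutate(lone, strand = "-", tss = 2.01e6)
  dm <- build_regulatory_domains(minus, g)
  expect_equal(dm$basal_start, 2.01e6 - 1000)
  expect_equal(dm$basal_end, 2.01e6 + 5000)
  expect_error(build_regulatory_domains(dplyr::bind_rows(lone, lone), g),
               "duplicate")
})

test_that("extensions never invade another gene's basal domain", {
  withr::local_seed(66)
  for (i in 1:10) {
    cfg <- small_sim_config(seed = 100 + i)
    gen <- simulate_genome(cfg)
    d <- build_regulatory_domains(gen$genes, gen$genome)
    basal <- tibble::tibble(chrom = d$chrom, start = d$basal_start,
                            end = d$basal_end)
    for (k in sample(nrow(d), min(20, nrow(d)))) {
      ext_only <- subtract_intervals(
        tibble::tibble(chrom = d$chrom[k], start = d$ext_start[k],
                       end = d$ext_end[k]),
        tibble::tibble(chrom = d$chrom[k], start = d$basal_start[k],
                       end = d$basal_end[k]))
      others <- normalize_intervals(basal[-k, ])
      expect_equal(interval_bp(intersect_intervals(ext_only, others)), 0)
    }
  }
})

test_that("binomial region test matches exhaustive enumeration", {
  g <- hmc_genome("chr1", 1000)
  # p0 = 0.5, n = 3 regions, all midpoints inside -> P = 1/8, fold 2
  dom <- tibble::tibble(chrom = "chr1", start = 0, end = 500)
  regions <- tibble::tibble(chrom = "chr1", start = c(0, 100, 200),
                            end = c(50, 150, 250))
  r <- binomial_region_test(regions, dom, g)
  expect_equal(r$k, 3)
  expect_equal(r$raw_p, 0.125)
  expect_equal(r$fold, 2)
  # enumeration oracle over all 2^n outcomes for several (n, k, p0)
  enum_p <- function(n, k, p0) {
    sum(vapply(k:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j), 0))
  }
  for (n in c(2, 5, 10)) {
    for (p0 in c(0.2, 0.5)) {
      dom_n <- tibble::tibble(chrom = "chr1", start = 0, end = 1000 * p0)
      for (k in 0:n) {
        starts <- c(seq_len(k) * 10, 1000 * p0 + seq_len(n - k) * 10)
        regs <- tibble::tibble(chrom = "chr1", start = starts - 5,
                               end = starts + 5)
        r <- binomial_region_test(regs, dom_n, g)
        expect_equal(r$k, k)
        expect_equal(r$raw_p, if (k == 0) 1 else enum_p(n, k, p0))
      }
    }
  }
  # p0 = 1 -> raw_p 1, fold k/n
  whole <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  rw <- binomial_region_test(regions, whole, g)
  expect_equal(rw$raw_p, 1)
  expect_equal(rw$fold, 1)
})

test_that("hypergeometric test matches combinatorial enumeration", {
  universe <- paste0("g", 1:10)
  r <- hypergeometric_gene_test(paste0("g", 1:3), paste0("g", 1:5), universe)
  expect_equal(r$raw_p, choose(5, 3) / choose(10, 3))  # 1/12
  expect_equal(r$fold, 2)
  # term = universe -> p 1, fold 1
  r2 <- hypergeometric_gene_test(paste0("g", 1:3), universe, universe)
  expect_equal(r2$raw_p, 1)
  expect_equal(r2$fold, 1)
  # zero overlap
  r3 <- hypergeometric_gene_test("g1", c("g9", "g10"), universe)
  expect_equal(r3$raw_p, 1)
  expect_equal(r3$fold, 0)
  expect_error(hypergeometric_gene_test("zz", "g1", universe), "universe")
})

test_that("BH q-values match the hand-applied step-up", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.01, 0.04, 0.9)), c(0.03, 0.06, 0.9))
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  p <- c(0.001, 0.02, 0.5)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("rank_terms sorts by binomial p with term-id tie-break", {
  rows <- tibble::tibble(term_id = c("T3", "T1", "T2"),
                         binom_raw_p = c(0.5, 0.01, 0.01))
  r <- rank_terms(rows, 2)
  expect_equal(r$term_id, c("T1", "T2"))
  withr::local_seed(3)
  many <- tibble::tibble(term_id = sprintf("T%03d", 1:100),
                         binom_raw_p = round(runif(100), 2))
  full <- rank_terms(many, 100)
  ord <- order(many$binom_raw_p, many$term_id)
  expect_equal(full$term_id, many$term_id[ord])
})

test_that("the planted term tops the GREAT ranking on simulated data", {
  cfg <- small_sim_config(seed = 314)
  st <- simulate_study(cfg)
  fet <- call_blocks(st$peaks[st$peaks$cohort == "fetal", ], 2, st$genome)
  adu <- call_blocks(st$peaks[st$peaks$cohort == "adult", ], 2, st$genome)
  sp <- cohort_specific_blocks(fet, adu, genome = st$genome)
  gr <- great_enrichment(sp$a_only, st$genes, st$terms, st$genome)
  expect_equal(tidy(gr)$term_id[1], "T01")
  expect_gt(tidy(gr)$binom_fold[1], 1)
  tab <- tidy(gr)
  expect_true(all(tab$binom_fdr_q >= tab$binom_raw_p))
})
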