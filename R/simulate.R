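# Synthetic hydroxymethylome studies with known ground truth.
#
# The generator emulates the statistical structure of a two-cohort (fetal /
# adult) liver 5hmC study: cohort-shared consensus blocks plus sample-unique
# noise peaks, feature-biased placement (CpG island / shore / genic
# enrichment, repeat and sex-chromosome depletion), expression matrices with
# planted developmental groups, and binomially sampled TAB-Seq counts.
# Every sub-generator derives its own seed from the master seed by a fixed
# offset, so stages are individually reproducible.

#' Simulation configuration
#'
#' Returns the full configuration for [simulate_study()] with documented
#' defaults. Defaults mirror the study design the package targets: 8 fetal
#' and 7 adult samples, a 3 x 1 Mb toy genome whose last chromosome plays
#' the role of a sex chromosome, ~120 planted consensus blocks per cohort
#' (half shared between cohorts), per-sample detection probability 0.6 with
#' +/-50 bp peak-boundary jitter, feature-biased placement, and
#' developmental expression groups planted with a 3-fold cohort ratio.
#'
#' @param seed Master integer seed.
#' @param n_chroms,chrom_length Number of chromosomes and their common
#'   length in bp.
#' @param sex_chrom If `TRUE`, the last chromosome is named `chrX` and
#'   depleted of peaks by `sex_chrom_weight`.
#' @param sex_chrom_weight Placement weight multiplier for `chrX`.
#' @param n_fetal,n_adult Samples per cohort.
#' @param n_blocks Planted consensus blocks per cohort.
#' @param fraction_shared Fraction of planted blocks shared between cohorts.
#' @param block_length Min/max planted block length (bp).
#' @param block_gap Minimum gap enforced between planted blocks (bp).
#' @param detection_prob Probability that a sample detects a planted block.
#' @param peak_jitter Peak boundaries are jittered uniformly by up to this
#'   many bp per end.
#' @param noise_peaks Sample-unique noise peaks per sample.
#' @param noise_peak_length Min/max noise peak length (bp).
#' @param read_mean,read_dispersion Negative-binomial read counts per peak.
#' @param gene_length,gene_gap Min/max gene body length and intergenic gap.
#' @param mirna_per_mb,mirna_length,lncrna_per_mb,lncrna_length,enhancer_per_mb,enhancer_length,cgi_per_mb,cgi_length,repeat_per_mb,repeat_length
#'   Feature-track densities (count per Mb) and element lengths.
#' @param shore_flank CGI shore flank width (bp).
#' @param bias Named placement-weight multipliers per feature track
#'   (values > 1 enrich, < 1 deplete).
#' @param group_bias Placement-weight multiplier for cohort-specific blocks
#'   inside the bodies of their cohort's developmental genes (groups I/II
#'   for fetal, IV/V for adult).
#' @param n_group Named counts of genes planted in groups I, II, IV, V
#'   (group III takes every remaining non-silent gene).
#' @param n_silent_both Genes silent in both cohorts.
#' @param expr_base Min/max baseline expression mean (linear scale).
#' @param silent_level Mean expression of silent genes.
#' @param silent_threshold The detection floor separating silent from
#'   expressed genes in the simulated arrays (recorded in the truth table).
#' @param group_fold Planted cohort expression ratio for groups II/IV
#'   (must exceed the 2-fold classification boundary to be recoverable
#'   under noise).
#' @param sigma Log-normal per-sample expression noise (sd of log values).
#' @param n_terms,term_size Number of gene-set terms and min/max genes per
#'   term; term `T01` is the planted target term.
#' @param n_target_genes Genes of the planted target term, each hosting one
#'   fetal-only block.
#' @param tabseq_depth Binomial sampling depth per TAB-Seq site.
#' @param tabseq_samples Validation samples per cohort.
#' @return A list of class `hmc_sim_config`.
#' @export
simulate_config <- function(seed = 1L,
                            n_chroms = 3L, chrom_length = 1e6,
                            sex_chrom = TRUE, sex_chrom_weight = 0.3,
                            n_fetal = 8L, n_adult = 7L,
                            n_blocks = 120L, fraction_shared = 0.5,
                            block_length = c(1500L, 3000L), block_gap = 150L,
                            detection_prob = 0.6, peak_jitter = 50L,
                            noise_peaks = 40L,
                            noise_peak_length = c(400L, 1000L),
                            read_mean = 50, read_dispersion = 5,
                            gene_length = c(3000L, 8000L),
                            gene_gap = c(7000L, 15000L),
                            mirna_per_mb = 25, mirna_length = 1500L,
                            lncrna_per_mb = 20, lncrna_length = 3000L,
                            enhancer_per_mb = 15, enhancer_length = 1500L,
                            cgi_per_mb = 12, cgi_length = 1500L,
                            shore_flank = 2000L,
                            repeat_per_mb = 80, repeat_length = 800L,
                            bias = c(refseq_genes = 1.5, mirna = 8,
                                     lncrna = 0.15, enhancers = 8, cgi = 8,
                                     cgi_shores = 4, repeats = 0.15),
                            group_bias = 4,
                            n_group = c(I = 15L, II = 20L, IV = 20L, V = 15L),
                            n_silent_both = 10L,
                            expr_base = c(5, 20), silent_level = 0.05,
                            silent_threshold = 1, group_fold = 3,
                            sigma = 0.2,
                            n_terms = 20L, term_size = c(10L, 15L),
                            n_target_genes = 18L,
                            tabseq_depth = 500L, tabseq_samples = 4L) {
  cfg <- as.list(environment())
  # YAML-sourced configs arrive with maps as lists
  cfg$n_group <- unlist(cfg$n_group)
  cfg$bias <- unlist(cfg$bias)
  if (is.null(names(cfg$n_group)) ||
      !all(names(cfg$n_group) %in% c("I", "II", "IV", "V"))) {
    abort("`n_group` must be named with groups among I, II, IV, V")
  }
  stopifnot(cfg$detection_prob >= 0, cfg$detection_prob <= 1,
            cfg$fraction_shared >= 0, cfg$fraction_shared <= 1,
            all(cfg$bias >= 0), cfg$group_bias >= 0, cfg$sigma >= 0)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "hmc_sim_config")
}

sim_sample_ids <- function(config) {
  list(fetal = sprintf("F%02d", seq_len(config$n_fetal)),
       adult = sprintf("A%02d", seq_len(config$n_adult)))
}

runif_len <- function(n, range) {
  if (range[1] > range[2]) abort("length range must be increasing")
  as.integer(floor(runif(n, range[1], range[2] + 1)))
}

# Uniform feature placement: `count` elements of length `len`, chromosome
# chosen with probability proportional to its length. Elements may overlap
# each other; with `avoid` given, elements overlapping those intervals are
# redrawn (used to keep depleted tracks out of enriched feature space, as
# repeats and lncRNA genes largely sit outside genic/CGI regions).
place_feature_track <- function(count, len, genome, avoid = NULL,
                                max_rounds = 200L) {
  count <- as.integer(round(count))
  if (count <= 0) return(empty_intervals())
  if (len > max(genome$size)) {
    abort(sprintf("infeasible density: %d bp features exceed every chromosome",
                  len))
  }
  avoid_gr <- if (!is.null(avoid) && nrow(avoid) > 0) {
    ivl_to_gr(avoid, NULL, genome$chrom)
  }
  placed <- empty_intervals()
  need <- count
  for (round in seq_len(max_rounds)) {
    if (need <= 0) break
    ok <- which(genome$size >= len)
    ci <- ok[sample.int(length(ok), need, replace = TRUE,
                        prob = genome$size[ok])]
    start <- floor(runif(need) * (genome$size[ci] - len + 1))
    cand <- tibble(chrom = genome$chrom[ci], start = start, end = start + len)
    if (!is.null(avoid_gr)) {
      cand <- cand[!IRanges::overlapsAny(
        ivl_to_gr(cand, NULL, genome$chrom), avoid_gr), , drop = FALSE]
    }
    placed <- dplyr::bind_rows(placed, cand)
    need <- count - nrow(placed)
  }
  if (need > 0) {
    abort("infeasible density: not enough free genome for the feature track")
  }
  normalize_intervals(placed, genome)
}

#' Generate a toy genome, feature tracks and gene models
#'
#' Places non-overlapping stranded genes along each chromosome, assigns
#' developmental group labels (I, II, IV, V, silent-in-both; the remainder
#' is group III), and draws miRNA, lncRNA, enhancer, CGI and repeat tracks
#' at the configured densities (CGI shores are derived as 2 kb flanks minus
#' the islands). Deterministic given the configuration seed.
#'
#' @param config An `hmc_sim_config` list.
#' @return A list: `genome` (tibble), `genes` (gene models with a `group`
#'   column), `features` (named list of normalized interval tibbles,
#'   including `refseq_genes` and `cgi_shores`).
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed + 1L, {
    chroms <- if (config$sex_chrom && config$n_chroms > 1) {
      c(sprintf("chr%d", seq_len(config$n_chroms - 1)), "chrX")
    } else {
      sprintf("chr%d", seq_len(config$n_chroms))
    }
    genome <- hmc_genome(chroms, rep(config$chrom_length, length(chroms)))
    genes <- dplyr::bind_rows(lapply(chroms, function(chr) {
      pos <- 0
      rows <- list()
      size <- config$chrom_length
      repeat {
        gap <- runif_len(1, config$gene_gap)
        len <- runif_len(1, config$gene_length)
        start <- pos + gap
        if (start + len > size - 1000) break
        rows[[length(rows) + 1]] <- tibble(chrom = chr, start = start,
                                           end = start + len)
        pos <- start + len
      }
      dplyr::bind_rows(rows)
    }))
    if (nrow(genes) == 0) abort("infeasible density: no genes fit the genome")
    genes$gene_id <- sprintf("g%03d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    need <- sum(config$n_group) + config$n_silent_both
    if (need > nrow(genes)) {
      abort(sprintf(
        "infeasible density: %d genes fit the genome but %d group labels requested",
        nrow(genes), need))
    }
    shuffled <- sample(genes$gene_id)
    labels <- c(rep(names(config$n_group), times = config$n_group),
                rep("silent", config$n_silent_both))
    group <- setNames(rep("III", nrow(genes)), genes$gene_id)
    group[shuffled[seq_along(labels)]] <- labels
    genes$group <- unname(group[genes$gene_id])
    mb <- genome_size(genome) / 1e6
    gene_track <- normalize_intervals(genes[c("chrom", "start", "end")],
                                      genome)
    cgi <- place_feature_track(config$cgi_per_mb * mb, config$cgi_length,
                               genome)
    shores <- cgi_shores(cgi, genome, config$shore_flank)
    # depleted tracks live outside genic/CGI space, as in real annotation
    enriched_space <- normalize_intervals(
      dplyr::bind_rows(gene_track, cgi, shores), genome)
    features <- list(
      refseq_genes = gene_track,
      mirna = place_feature_track(config$mirna_per_mb * mb,
                                  config$mirna_length, genome),
      lncrna = place_feature_track(config$lncrna_per_mb * mb,
                                   config$lncrna_length, genome,
                                   avoid = enriched_space),
      enhancers = place_feature_track(config$enhancer_per_mb * mb,
                                      config$enhancer_length, genome),
      cgi = cgi,
      cgi_shores = shores,
      repeats = place_feature_track(config$repeat_per_mb * mb,
                                    config$repeat_length, genome,
                                    avoid = enriched_space)
    )
    list(genome = genome, genes = genes[c("gene_id", "chrom", "strand",
                                          "tss", "start", "end", "group")],
         features = features)
  })
}

# Placement weight of candidate midpoints: the largest enrichment
# multiplier of any containing feature; if only depleted features contain
# the point, the smallest depletion multiplier; else 1.
feature_weight_fn <- function(features, bias, genome) {
  active <- names(bias)[names(bias) %in% names(features) & bias != 1]
  grs <- lapply(features[active], function(f) ivl_to_gr(f, genome))
  function(chrom, pos) {
    n <- length(pos)
    if (n == 0) return(numeric(0))
    pts <- ivl_to_gr(tibble(chrom = chrom, start = pos, end = pos + 1),
                     genome)
    enr <- rep(NA_real_, n)
    dep <- rep(NA_real_, n)
    for (nm in active) {
      inside <- IRanges::overlapsAny(pts, grs[[nm]])
      m <- bias[[nm]]
      if (m > 1) {
        enr[inside] <- pmax(enr[inside], m, na.rm = TRUE)
      } else {
        dep[inside] <- pmin(dep[inside], m, na.rm = TRUE)
      }
    }
    w <- rep(1, n)
    w[!is.na(dep)] <- dep[!is.na(dep)]
    w[!is.na(enr)] <- enr[!is.na(enr)]
    w
  }
}

chrom_weights <- function(config, genome) {
  w <- genome$size
  if (config$sex_chrom) w[genome$chrom == "chrX"] <- w[genome$chrom == "chrX"] *
      config$sex_chrom_weight
  w
}

# Rejection-sample `n` intervals with placement probability proportional to
# weight_fn at the midpoint. With `disjoint = TRUE` the intervals are kept
# mutually >= `gap` bp apart (and apart from `avoid`).
draw_biased_intervals <- function(n, len_range, genome, chrom_w, weight_fn,
                                  w_max, gap = 0L, avoid = NULL,
                                  disjoint = TRUE, max_rounds = 2000L) {
  accepted <- if (is.null(avoid)) empty_intervals() else {
    avoid[c("chrom", "start", "end")]
  }
  n_avoid <- nrow(accepted)
  rounds <- 0
  while (nrow(accepted) - n_avoid < n) {
    rounds <- rounds + 1
    if (rounds > max_rounds) {
      abort("placement did not converge; genome too crowded for the requested blocks")
    }
    remaining <- n - (nrow(accepted) - n_avoid)
    batch <- max(200L, 4L * remaining)
    len <- runif_len(batch, len_range)
    ci <- sample.int(nrow(genome), batch, replace = TRUE, prob = chrom_w)
    fits <- genome$size[ci] - len + 1 > 0
    len <- len[fits]; ci <- ci[fits]
    if (length(len) == 0) next
    start <- floor(runif(length(len)) * (genome$size[ci] - len + 1))
    cand <- tibble(chrom = genome$chrom[ci], start = start,
                   end = start + len)
    mid <- cand$start + (cand$end - cand$start) %/% 2
    w <- weight_fn(cand$chrom, mid)
    keep <- runif(length(w)) < w / w_max
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) next
    if (!disjoint) {
      take <- min(remaining, nrow(cand))
      accepted <- dplyr::bind_rows(accepted, cand[seq_len(take), ])
      next
    }
    # drop candidates within `gap` of anything already accepted
    if (nrow(accepted) > 0) {
      pad <- tibble(chrom = accepted$chrom,
                    start = pmax(0, accepted$start - gap),
                    end = accepted$end + gap)
      free <- !IRanges::overlapsAny(ivl_to_gr(cand, NULL, genome$chrom),
                                    ivl_to_gr(pad, NULL, genome$chrom))
      cand <- cand[free, , drop = FALSE]
      if (nrow(cand) == 0) next
    }
    # greedy independent set within the batch (gap-padded)
    ord <- order(cand$chrom, cand$start)
    cand <- cand[ord, , drop = FALSE]
    last_chrom <- ""
    last_end <- -Inf
    sel <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (cand$chrom[i] != last_chrom || cand$start[i] >= last_end + gap) {
        sel[i] <- TRUE
        last_chrom <- cand$chrom[i]
        last_end <- cand$end[i]
      }
    }
    cand <- cand[sel, , drop = FALSE]
    take <- min(remaining, nrow(cand))
    accepted <- dplyr::bind_rows(accepted, cand[seq_len(take), ])
  }
  accepted[seq(n_avoid + 1, n_avoid + n), , drop = FALSE]
}

#' Plant the cohort consensus blocks
#'
#' Plants mutually disjoint "true" blocks: a shared set present in both
#' cohorts (feature-biased placement), fetal-specific blocks biased toward
#' group I/II gene bodies, adult-specific blocks toward group IV/V bodies,
#' and one guaranteed fetal-only block inside each of the
#' `n_target_genes` target-term genes.
#'
#' @param config An `hmc_sim_config`.
#' @param gen Output of [simulate_genome()].
#' @return A list: `blocks` (tibble `chrom`, `start`, `end`, `cohort` in
#'   shared/fetal/adult, `target` flag) and `target_genes` (character).
#' @export
simulate_blocks <- function(config, gen) {
  withr::with_seed(config$seed + 2L, {
    genome <- gen$genome
    genes <- gen$genes
    wfn <- feature_weight_fn(gen$features, config$bias, genome)
    cw <- chrom_weights(config, genome)
    enr_max <- max(c(config$bias[config$bias > 1], 1))
    n_shared <- as.integer(round(config$n_blocks * config$fraction_shared))
    n_spec <- config$n_blocks - n_shared

    # target-term genes: group I/II bodies roomy enough for a block
    fet_genes <- genes[genes$group %in% c("I", "II"), ]
    roomy <- fet_genes[(fet_genes$end - fet_genes$start) >=
                         config$block_length[1] + 300, ]
    if (nrow(roomy) < config$n_target_genes) {
      abort("not enough group I/II genes to host the target term")
    }
    target <- roomy[sample.int(nrow(roomy), config$n_target_genes), ]
    tlen <- pmin(runif_len(nrow(target), config$block_length),
                 (target$end - target$start) - 200L)
    toff <- floor(runif(nrow(target)) *
                    ((target$end - target$start) - tlen - 100) ) + 50
    target_blocks <- tibble(chrom = target$chrom,
                            start = target$start + toff,
                            end = target$start + toff + tlen)

    group_extra_fn <- function(group_set) {
      bodies <- normalize_intervals(
        genes[genes$group %in% group_set, c("chrom", "start", "end")], genome)
      bgr <- ivl_to_gr(bodies, genome)
      function(chrom, pos) {
        pts <- ivl_to_gr(tibble(chrom = chrom, start = pos, end = pos + 1),
                         genome)
        w <- wfn(chrom, pos)
        inside <- IRanges::overlapsAny(pts, bgr)
        w * ifelse(inside, config$group_bias, 1)
      }
    }

    n_target <- nrow(target_blocks)
    fetal_extra <- min(n_spec - n_target, n_spec)
    if (fetal_extra < 0) abort("n_target_genes exceeds cohort-specific block quota")
    fetal_spec <- draw_biased_intervals(
      fetal_extra, config$block_length, genome, cw,
      group_extra_fn(c("I", "II")), enr_max * config$group_bias,
      gap = config$block_gap, avoid = target_blocks)
    acc <- dplyr::bind_rows(target_blocks, fetal_spec)
    adult_spec <- draw_biased_intervals(
      n_spec, config$block_length, genome, cw,
      group_extra_fn(c("IV", "V")), enr_max * config$group_bias,
      gap = config$block_gap, avoid = acc)
    acc <- dplyr::bind_rows(acc, adult_spec)
    shared <- draw_biased_intervals(
      n_shared, config$block_length, genome, cw, wfn, enr_max,
      gap = config$block_gap, avoid = acc)
    blocks <- dplyr::bind_rows(
      dplyr::mutate(target_blocks, cohort = "fetal", target = TRUE),
      dplyr::mutate(fetal_spec, cohort = "fetal", target = FALSE),
      dplyr::mutate(adult_spec, cohort = "adult", target = FALSE),
      dplyr::mutate(shared, cohort = "shared", target = FALSE)
    )
    list(blocks = blocks, target_genes = target$gene_id)
  })
}

#' Generate per-sample peak sets from planted blocks
#'
#' Each sample detects each of its cohort's planted blocks independently
#' with probability `detection_prob`; a detected block becomes a peak with
#' both boundaries jittered uniformly by up to `peak_jitter` bp (truncated
#' at chromosome ends). Sample-unique noise peaks are added with
#' feature-biased placement, and every peak receives a negative-binomial
#' read count.
#'
#' @param config An `hmc_sim_config`.
#' @param gen Output of [simulate_genome()].
#' @param truth Output of [simulate_blocks()].
#' @return A long peak tibble: `chrom`, `start`, `end`, `sample_id`,
#'   `cohort`, `reads`.
#' @export
simulate_peaks <- function(config, gen, truth) {
  withr::with_seed(config$seed + 3L, {
    genome <- gen$genome
    ids <- sim_sample_ids(config)
    wfn <- feature_weight_fn(gen$features, config$bias, genome)
    cw <- chrom_weights(config, genome)
    enr_max <- max(c(config$bias[config$bias > 1], 1))
    sizes <- setNames(genome$size, genome$chrom)
    out <- list()
    for (cohort in c("fetal", "adult")) {
      planted <- truth$blocks[truth$blocks$cohort %in% c("shared", cohort), ]
      n_coh <- length(ids[[cohort]])
      all_noise <- if (config$noise_peaks > 0) {
        draw_biased_intervals(config$noise_peaks * n_coh,
                              config$noise_peak_length, genome, cw, wfn,
                              enr_max, disjoint = FALSE)
      } else {
        empty_intervals()
      }
      noise_of <- split(all_noise,
                        rep(seq_len(n_coh), each = config$noise_peaks))
      for (s_i in seq_along(ids[[cohort]])) {
        sid <- ids[[cohort]][s_i]
        det <- planted[runif(nrow(planted)) < config$detection_prob, ,
                       drop = FALSE]
        if (nrow(det) > 0) {
          j <- config$peak_jitter
          s <- det$start + runif_len(nrow(det), c(-j, j))
          e <- det$end + runif_len(nrow(det), c(-j, j))
          s <- pmax(0, s)
          e <- pmin(unname(sizes[det$chrom]), e)
          keep <- s < e
          det <- tibble(chrom = det$chrom[keep], start = s[keep],
                        end = e[keep])
        } else {
          det <- empty_intervals()
        }
        noise <- if (config$noise_peaks > 0) noise_of[[s_i]] else {
          empty_intervals()
        }
        pk <- dplyr::bind_rows(det, noise)
        if (nrow(pk) > 0) {
          pk$sample_id <- sid
          pk$cohort <- cohort
          pk$reads <- rnbinom(nrow(pk), size = config$read_dispersion,
                              mu = config$read_mean) + 1
          out[[length(out) + 1]] <- pk
        }
      }
    }
    peaks <- dplyr::bind_rows(out)
    if (nrow(peaks) == 0) {
      return(tibble(chrom = character(), start = integer(), end = integer(),
                    sample_id = character(), cohort = character(),
                    reads = numeric()))
    }
    normalize_peaks(peaks, genome)
  })
}

#' Generate the cohort expression matrix
#'
#' Per-gene cohort means are set by the planted group: group I genes are
#' expressed in the fetal cohort and silent (at `silent_level`) in adults,
#' group V the mirror image; groups II/IV have a `group_fold` cohort ratio;
#' group III and both-silent genes are flat. Per-sample values multiply the
#' cohort mean by log-normal noise `exp(N(0, sigma^2))`.
#'
#' @param config An `hmc_sim_config`.
#' @param gen Output of [simulate_genome()].
#' @return A list: `expression` (tibble `gene_id` + one column per sample)
#'   and `sample_info` (tibble `sample_id`, `cohort`).
#' @export
simulate_expression <- function(config, gen) {
  withr::with_seed(config$seed + 4L, {
    genes <- gen$genes
    n <- nrow(genes)
    base <- runif(n, config$expr_base[1], config$expr_base[2])
    sl <- config$silent_level
    gf <- config$group_fold
    fetal_mean <- dplyr::case_when(
      genes$group == "I" ~ base,
      genes$group == "II" ~ base * gf,
      genes$group == "IV" ~ base,
      genes$group == "V" ~ sl,
      genes$group == "silent" ~ sl,
      TRUE ~ base
    )
    adult_mean <- dplyr::case_when(
      genes$group == "I" ~ sl,
      genes$group == "II" ~ base,
      genes$group == "IV" ~ base * gf,
      genes$group == "V" ~ base,
      genes$group == "silent" ~ sl,
      TRUE ~ base
    )
    ids <- sim_sample_ids(config)
    expr <- tibble(gene_id = genes$gene_id)
    for (sid in ids$fetal) {
      expr[[sid]] <- fetal_mean * exp(rnorm(n, 0, config$sigma))
    }
    for (sid in ids$adult) {
      expr[[sid]] <- adult_mean * exp(rnorm(n, 0, config$sigma))
    }
    sample_info <- tibble(
      sample_id = c(ids$fetal, ids$adult),
      cohort = c(rep("fetal", config$n_fetal), rep("adult", config$n_adult))
    )
    list(expression = expr, sample_info = sample_info)
  })
}

#' Generate gene-set terms with one planted target term
#'
#' Term `T01` contains exactly the target genes (each hosting a planted
#' fetal-only block); the remaining terms draw genes uniformly from the
#' whole gene universe.
#'
#' @param config An `hmc_sim_config`.
#' @param gen Output of [simulate_genome()].
#' @param truth Output of [simulate_blocks()].
#' @return A term tibble `term_id`, `term_name`, `gene_id`.
#' @export
simulate_terms <- function(config, gen, truth) {
  withr::with_seed(config$seed + 5L, {
    rows <- list(tibble(term_id = "T01",
                        term_name = "planted fetal developmental pathway",
                        gene_id = truth$target_genes))
    if (config$n_terms > 1) for (i in seq(2, config$n_terms)) {
      sz <- runif_len(1, config$term_size)
      rows[[i]] <- tibble(
        term_id = sprintf("T%02d", i),
        term_name = sprintf("background pathway %02d", i),
        gene_id = sample(gen$genes$gene_id, sz)
      )
    }
    dplyr::bind_rows(rows)
  })
}

#' Generate single-base TAB-Seq validation counts
#'
#' Two validation intervals mimic the study design: one inside a planted
#' fetal-only block (4 CpG sites, high fetal 5hmC) and one inside a planted
#' adult-only block (7 CpG sites, high adult 5hmC). For each validation
#' sample and site, oxidized counts are Binomial(depth, h) and untreated
#' bisulfite counts Binomial(depth, h + m), for planted per-sample levels
#' (h, m).
#'
#' @param config An `hmc_sim_config`.
#' @param gen Output of [simulate_genome()].
#' @param truth Output of [simulate_blocks()].
#' @return A list: `sites` (counts per sample and CpG), `intervals` (the
#'   two validation intervals with their hydroxymethylated cohort), and
#'   `truth` (planted per-sample, per-site `h` and `m`).
#' @export
simulate_tabseq <- function(config, gen, truth) {
  withr::with_seed(config$seed + 6L, {
    fetal_blk <- truth$blocks[truth$blocks$cohort == "fetal", ][1, ]
    adult_blk <- truth$blocks[truth$blocks$cohort == "adult", ][1, ]
    if (any(is.na(fetal_blk$chrom)) || any(is.na(adult_blk$chrom))) {
      abort("need at least one fetal-only and one adult-only planted block")
    }
    intervals <- tibble(
      interval_id = c("iv_fetal", "iv_adult"),
      chrom = c(fetal_blk$chrom, adult_blk$chrom),
      start = c(fetal_blk$start + 100, adult_blk$start + 100),
      end = c(fetal_blk$start + 100 + 4 * 40, adult_blk$start + 100 + 7 * 40),
      n_cpg = c(4L, 7L),
      hmc_cohort = c("fetal", "adult")
    )
    ids <- sim_sample_ids(config)
    vs <- tibble(
      sample_id = c(head(ids$fetal, config$tabseq_samples),
                    head(ids$adult, config$tabseq_samples)),
      cohort = rep(c("fetal", "adult"), each = config$tabseq_samples)
    )
    rows <- list(); truths <- list()
    for (i in seq_len(nrow(intervals))) {
      iv <- intervals[i, ]
      pos <- iv$start + 10 + (seq_len(iv$n_cpg) - 1) * 40
      for (s in seq_len(nrow(vs))) {
        high <- vs$cohort[s] == iv$hmc_cohort
        h <- if (!high) runif(1, 0.01, 0.05)
             else if (iv$hmc_cohort == "adult") runif(1, 0.45, 0.55)
             else runif(1, 0.25, 0.35)
        m <- runif(1, 0.15, 0.30)
        d <- config$tabseq_depth
        ox_c <- rbinom(iv$n_cpg, d, h)
        bs_c <- rbinom(iv$n_cpg, d, min(1, h + m))
        rows[[length(rows) + 1]] <- tibble(
          sample_id = vs$sample_id[s], cohort = vs$cohort[s],
          interval_id = iv$interval_id, chrom = iv$chrom, pos = pos,
          ox_c = ox_c, ox_t = d - ox_c, bs_c = bs_c, bs_t = d - bs_c
        )
        truths[[length(truths) + 1]] <- tibble(
          sample_id = vs$sample_id[s], interval_id = iv$interval_id,
          chrom = iv$chrom, pos = pos, h = h, m = m
        )
      }
    }
    list(sites = dplyr::bind_rows(rows),
         intervals = intervals,
         truth = dplyr::bind_rows(truths))
  })
}

#' Simulate a complete two-cohort hydroxymethylome study
#'
#' Runs every sub-generator under seeds derived from the master seed and
#' returns the study plus its full ground truth. Identical configurations
#' produce identical studies.
#'
#' @param config An `hmc_sim_config` (see [simulate_config()]).
#' @return A list: `config`, `genome`, `genes`, `features`, `peaks`,
#'   `expression`, `sample_info`, `terms`, `tabseq` (sites/intervals), and
#'   `truth` (planted blocks, target genes, gene groups, silence threshold,
#'   TAB-Seq levels).
#' @export
simulate_study <- function(config = simulate_config()) {
  if (!inherits(config, "hmc_sim_config")) {
    abort("`config` must come from simulate_config()")
  }
  gen <- simulate_genome(config)
  blk <- simulate_blocks(config, gen)
  peaks <- simulate_peaks(config, gen, blk)
  ex <- simulate_expression(config, gen)
  terms <- simulate_terms(config, gen, blk)
  ts <- simulate_tabseq(config, gen, blk)
  list(
    config = config,
    genome = gen$genome,
    genes = gen$genes,
    features = gen$features,
    peaks = peaks,
    expression = ex$expression,
    sample_info = ex$sample_info,
    terms = terms,
    tabseq = list(sites = ts$sites, intervals = ts$intervals),
    truth = list(
      blocks = blk$blocks,
      target_genes = blk$target_genes,
      gene_groups = gen$genes[c("gene_id", "group")],
      silent_threshold = config$silent_threshold,
      tabseq = ts$truth
    )
  )
}

#' Write a simulated study to disk
#'
#' Emits exactly the plain-text inputs the analysis functions read back:
#' genome TSV, one BED per feature track, one BED5 per sample (score =
#' reads) plus a cohort manifest, gene models, expression matrix, term
#' membership, TAB-Seq counts, and the ground truth as JSON.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return A named list of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "features"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    genes = file.path(dir, "genes.tsv"),
    expression = file.path(dir, "expression.tsv"),
    terms = file.path(dir, "terms.tsv"),
    tabseq = file.path(dir, "tabseq.tsv"),
    truth = file.path(dir, "truth.json"),
    features_dir = file.path(dir, "features"),
    peaks_dir = file.path(dir, "peaks")
  )
  write_genome(study$genome, paths$genome)
  for (nm in names(study$features)) {
    write_bed(study$features[[nm]], file.path(dir, "features",
                                              paste0(nm, ".bed")))
  }
  manifest <- study$sample_info
  manifest$bed_path <- file.path("peaks", paste0(manifest$sample_id, ".bed"))
  for (i in seq_len(nrow(manifest))) {
    pk <- study$peaks[study$peaks$sample_id == manifest$sample_id[i], ]
    pk <- dplyr::rename(pk[c("chrom", "start", "end", "reads")],
                        score = "reads")
    write_bed(pk, file.path(dir, manifest$bed_path[i]))
  }
  readr::write_tsv(manifest[c("sample_id", "cohort", "bed_path")],
                   paths$manifest)
  write_gene_models(study$genes, paths$genes)
  readr::write_tsv(study$expression, paths$expression)
  readr::write_tsv(study$terms, paths$terms)
  readr::write_tsv(study$tabseq$sites, paths$tabseq)
  truth <- study$truth
  truth$tabseq_intervals <- study$tabseq$intervals
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
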