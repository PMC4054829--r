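# Single-base TAB-Seq arithmetic. The oxidized-sample C/(C+T) ratio at a
# CpG reads out 5hmC directly; the untreated bisulfite ratio reads out
# 5mC + 5hmC, so their difference gives 5mC (clipped at 0 against sampling
# noise).

#' Separate 5hmC and 5mC levels at a CpG site
#'
#' `hmc_level = ox_ratio`; `mc_level = max(0, bs_ratio - ox_ratio)`.
#' Vectorized over sites.
#'
#' @param ox_ratio C/(C+T) ratio from the TET-oxidized, bisulfite-converted
#'   sample, in \[0, 1\].
#' @param bs_ratio C/(C+T) ratio from the untreated bisulfite sample, in
#'   \[0, 1\].
#' @return A tibble `hmc_level`, `mc_level`.
#' @examples
#' site_levels(0.30, 0.50)
#' @export
site_levels <- function(ox_ratio, bs_ratio) {
  if (any(is.na(ox_ratio)) || any(ox_ratio < 0) || any(ox_ratio > 1) ||
      any(is.na(bs_ratio)) || any(bs_ratio < 0) || any(bs_ratio > 1)) {
    abort("ratios must lie in [0, 1]")
  }
  tibble(hmc_level = ox_ratio, mc_level = pmax(0, bs_ratio - ox_ratio))
}

#' Compute per-site methylation levels from TAB-Seq counts
#'
#' Takes per-CpG oxidized and untreated C/T counts, forms the C/(C+T)
#' ratios, and separates 5hmC and 5mC levels via [site_levels()]. Sites with
#' zero depth in either assay are rejected.
#'
#' @param sites Tibble with columns `ox_c`, `ox_t`, `bs_c`, `bs_t`
#'   (non-negative integer counts); any other columns (`chrom`, `pos`,
#'   `sample_id`, ...) are carried through.
#' @return `sites` with added columns `ox_ratio`, `bs_ratio`, `hmc_level`,
#'   `mc_level`.
#' @export
tabseq_levels <- function(sites) {
  need <- c("ox_c", "ox_t", "bs_c", "bs_t")
  if (!is.data.frame(sites) || !all(need %in% names(sites))) {
    abort("`sites` needs count columns ox_c, ox_t, bs_c, bs_t")
  }
  counts <- sites[need]
  if (any(vapply(counts, function(v) any(is.na(v) | v < 0), TRUE))) {
    abort("counts must be non-negative")
  }
  ox_d <- sites$ox_c + sites$ox_t
  bs_d <- sites$bs_c + sites$bs_t
  bad <- which(ox_d == 0 | bs_d == 0)
  if (length(bad)) {
    abort(sprintf("site row %d has zero sequencing depth", bad[1]))
  }
  sites$ox_ratio <- sites$ox_c / ox_d
  sites$bs_ratio <- sites$bs_c / bs_d
  lv <- site_levels(sites$ox_ratio, sites$bs_ratio)
  sites$hmc_level <- lv$hmc_level
  sites$mc_level <- lv$mc_level
  sites
}

#' Read a TAB-Seq site table
#'
#' TSV with header columns `chrom`, `pos` (0-based CpG C position), `ox_c`,
#' `ox_t`, `bs_c`, `bs_t`, and optionally `sample_id` / `interval_id`.
#'
#' @param path File path.
#' @return A tibble of sites.
#' @export
read_tabseq <- function(path) {
  if (!file.exists(path)) abort(paste0("TAB-Seq table not found: ", path))
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "d", ox_c = "d", ox_t = "d", bs_c = "d", bs_t = "d",
    .default = "c"), progress = FALSE)
}

#' Mean methylation levels over an interval
#'
#' Unweighted mean of per-site 5hmC and 5mC levels over the CpG sites falling
#' inside each interval (an interval with no sites is an error).
#'
#' @param sites Tibble with `chrom`, `pos`, `hmc_level`, `mc_level` (e.g.
#'   from [tabseq_levels()]), typically for a single sample.
#' @param intervals Interval tibble; an `interval_id` column is carried
#'   through if present.
#' @return One row per interval: `interval_id` (when present), `chrom`,
#'   `start`, `end`, `n_cpg`, `mean_hmc`, `mean_mc`.
#' @export
interval_mean <- function(sites, intervals) {
  need <- c("chrom", "pos", "hmc_level", "mc_level")
  if (!is.data.frame(sites) || !all(need %in% names(sites))) {
    abort("`sites` needs columns chrom, pos, hmc_level, mc_level")
  }
  check_interval_frame(intervals, "intervals")
  rows <- purrr::map(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    inside <- sites$chrom == iv$chrom & sites$pos >= iv$start &
      sites$pos < iv$end
    if (!any(inside)) {
      abort(sprintf("no CpG sites inside interval %s:%d-%d",
                    iv$chrom, iv$start, iv$end))
    }
    out <- tibble(
      chrom = iv$chrom, start = iv$start, end = iv$end,
      n_cpg = sum(inside),
      mean_hmc = mean(sites$hmc_level[inside]),
      mean_mc = mean(sites$mc_level[inside])
    )
    if ("interval_id" %in% names(intervals)) {
      out <- dplyr::bind_cols(tibble(interval_id = iv$interval_id), out)
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Concordance of block calls with TAB-Seq levels
#'
#' On a sample-by-interval grid, a cell is TAB-Seq positive iff its mean
#' 5hmC level reaches `call_threshold`. Confusion counts are relative to the
#' sequencing-based calls: `fp` counts cells called positive by peaks/blocks
#' but TAB-Seq negative (false positive peaks), `fn` the reverse.
#'
#' @param grid Tibble with one row per sample-interval cell: `sample_id`,
#'   `interval_id`, `ngs_positive` (logical block/peak call), `mean_hmc`.
#' @param call_threshold 5hmC level above which TAB-Seq calls a cell
#'   hydroxymethylated (default 0.1).
#' @return A one-row tibble `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
tabseq_concordance <- function(grid, call_threshold = 0.1) {
  need <- c("sample_id", "interval_id", "ngs_positive", "mean_hmc")
  if (!is.data.frame(grid) || !all(need %in% names(grid))) {
    abort("`grid` needs columns sample_id, interval_id, ngs_positive, mean_hmc")
  }
  if (anyDuplicated(grid[c("sample_id", "interval_id")])) {
    abort("duplicated sample/interval cells in `grid`")
  }
  if (any(is.na(grid$ngs_positive)) || any(is.na(grid$mean_hmc))) {
    abort("`grid` has missing calls or levels")
  }
  tab <- grid$mean_hmc >= call_threshold
  ngs <- as.logical(grid$ngs_positive)
  tibble(
    tp = sum(ngs & tab), fp = sum(ngs & !tab),
    fn = sum(!ngs & tab), tn = sum(!ngs & !tab),
    n = nrow(grid)
  )
}
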