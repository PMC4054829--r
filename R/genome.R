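#' Declare a genome as an ordered set of chromosomes
#'
#' All interval arithmetic and enrichment statistics in hmcblocks are computed
#' relative to a declared genome: an ordered table of chromosome names and
#' lengths. Intervals on chromosomes absent from the declaration are an error
#' everywhere, which surfaces annotation/genome mismatches early.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param size Integer vector of chromosome lengths in bp (all > 0).
#'
#' @return A tibble with columns `chrom` and `size`.
#' @examples
#' hmc_genome(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
hmc_genome <- function(chrom, size) {
  chrom <- as.character(chrom)
  size <- as.numeric(size)
  if (length(chrom) != length(size)) {
    abort("`chrom` and `size` must have the same length")
  }
  if (anyDuplicated(chrom)) {
    abort(paste0(
      "duplicated chromosome name(s): ",
      paste(unique(chrom[duplicated(chrom)]), collapse = ", ")
    ))
  }
  if (any(is.na(size)) || any(size <= 0)) {
    abort("all chromosome sizes must be positive")
  }
  tibble(chrom = chrom, size = size)
}

#' Read or write a genome file
#'
#' Genome files are two-column tab-separated text: `chrom<TAB>length`, no
#' header.
#'
#' @param path Path to a genome TSV.
#' @return `read_genome()` returns a genome tibble (columns `chrom`, `size`);
#'   `write_genome()` returns `path` invisibly.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("genome file not found: ", path))
  x <- readr::read_tsv(path, col_names = c("chrom", "size"),
                       col_types = readr::cols(readr::col_character(),
                                               readr::col_double()),
                       progress = FALSE)
  hmc_genome(x$chrom, x$size)
}

#' @rdname read_genome
#' @param genome A genome tibble.
#' @export
write_genome <- function(genome, path) {
  check_genome(genome)
  readr::write_tsv(genome, path, col_names = FALSE)
  invisible(path)
}

#' Total genome size in bp
#'
#' @param genome A genome tibble.
#' @return Total length of all chromosomes in bp.
#' @export
genome_size <- function(genome) {
  check_genome(genome)
  sum(genome$size)
}

check_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("chrom", "size") %in% names(genome))) {
    abort("`genome` must be a data frame with columns `chrom` and `size`")
  }
  invisible(hmc_genome(genome$chrom, genome$size))
}
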