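# End-to-end pipeline: simulate -> call blocks -> cohort-specific blocks ->
# feature enrichment -> expression groups -> developmental enrichment ->
# GREAT-style terms -> TAB-Seq validation. One master seed drives every
# stage; rerunning with the same configuration reproduces every output file
# byte for byte (timestamps excluded from the comparable report counts).

#' Default pipeline configuration
#'
#' @param seed Master integer seed.
#' @return A nested list: `seed`, `simulation` (overrides passed to
#'   [simulate_config()]) and `analysis` (`min_support`, `n_perm`,
#'   `silent_threshold`, `fold`, `call_threshold`, `top_terms`).
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulation = list(),
    analysis = list(
      min_support = 2L,
      n_perm = 1000L,
      silent_threshold = 1,
      fold = 2,
      call_threshold = 0.1,
      top_terms = 10L
    )
  )
}

validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), c("seed", "simulation", "analysis"))
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    abort("config must declare an integer `seed`")
  }
  base <- default_pipeline_config(config$seed)
  base$simulation <- config$simulation %||% list()
  unknown <- setdiff(names(base$simulation),
                     names(formals(simulate_config)))
  if (length(unknown)) {
    abort(paste0("unknown simulation field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  for (nm in names(config$analysis %||% list())) {
    if (!nm %in% names(base$analysis)) {
      abort(paste0("unknown analysis field: ", nm))
    }
    base$analysis[[nm]] <- config$analysis[[nm]]
  }
  base
}

run_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full analysis pipeline on a simulated study
#'
#' Executes every stage in dependency order under a single master seed,
#' writing all intermediate tables under `out_dir` and a machine-readable
#' JSON run report. Each analysis stage reads the files the previous stage
#' wrote (not in-memory objects), so the emitted files are verified to be
#' valid inputs on every run. Any stage failure aborts with the failing
#' stage named.
#'
#' @param config A config list (see [default_pipeline_config()]) or the
#'   path to a YAML file with the same structure.
#' @param out_dir Output directory.
#' @return The run report (a list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_pipeline_config(config)
  an <- config$analysis
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  paths <- run_stage("simulate", {
    cfg <- do.call(simulate_config,
                   c(list(seed = config$seed), config$simulation))
    study <- simulate_study(cfg)
    write_study(study, file.path(out_dir, "data"))
  })

  env <- new.env()
  run_stage("load-inputs", {
    env$genome <- read_genome(paths$genome)
    env$manifest <- read_manifest(paths$manifest)
    env$peaks <- read_peak_sets(env$manifest, env$genome)
    env$genes <- read_gene_models(paths$genes)
    env$features <- lapply(
      setNames(nm = sub("\\.bed$", "",
                        list.files(paths$features_dir, pattern = "\\.bed$"))),
      function(nm) read_bed(file.path(paths$features_dir,
                                      paste0(nm, ".bed")), env$genome))
    invisible(NULL)
  })

  block_files <- run_stage("call-blocks", {
    out <- list()
    for (cohort in c("fetal", "adult")) {
      pk <- env$peaks[env$peaks$cohort == cohort, ]
      bl <- call_blocks(pk, min_support = an$min_support, genome = env$genome)
      f <- file.path(out_dir, paste0("blocks_", cohort, ".tsv"))
      write_blocks(bl, f)
      out[[cohort]] <- f
    }
    out
  })
  env$blocks <- lapply(block_files, read_blocks)

  sharing <- run_stage("peak-sharing", {
    lapply(setNames(nm = c("fetal", "adult")), function(cohort) {
      classify_peak_sharing(env$peaks[env$peaks$cohort == cohort, ],
                            genome = env$genome)
    })
  })

  diff_files <- run_stage("diff-blocks", {
    sp <- cohort_specific_blocks(env$blocks$fetal, env$blocks$adult,
                                 genome = env$genome)
    f1 <- file.path(out_dir, "blocks_fetal_only.tsv")
    f2 <- file.path(out_dir, "blocks_adult_only.tsv")
    write_blocks(sp$a_only, f1)
    write_blocks(sp$b_only, f2)
    list(fetal_only = f1, adult_only = f2)
  })
  env$fetal_only <- read_blocks(diff_files$fetal_only)
  env$adult_only <- read_blocks(diff_files$adult_only)

  enrich_file <- run_stage("enrich", {
    rows <- list()
    for (cohort in c("fetal", "adult")) {
      for (nm in names(env$features)) {
        pe <- permutation_enrichment(env$blocks[[cohort]],
                                     env$features[[nm]], env$genome,
                                     n_perm = an$n_perm,
                                     seed = config$seed, name = nm)
        ae <- analytic_enrichment(env$blocks[[cohort]], env$features[[nm]],
                                  env$genome, name = nm)
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble(cohort = cohort),
          dplyr::select(tidy(pe), "feature", "observed_bp", "perm_mean_bp",
                        "null_p", "n_perm", "seed"),
          tibble(fold = tidy(ae)$fold,
                 expected_bp = tidy(ae)$expected_bp)
        )
      }
    }
    f <- file.path(out_dir, "feature_enrichment.tsv")
    readr::write_tsv(dplyr::bind_rows(rows), f)
    f
  })

  expr_file <- run_stage("expr-groups", {
    expr <- read_expression(paths$expression)
    cls <- classify_expression(expr, env$manifest,
                               silent_threshold = an$silent_threshold,
                               fold = an$fold)
    f <- file.path(out_dir, "gene_classes.tsv")
    readr::write_tsv(cls, f)
    f
  })
  env$gene_classes <- readr::read_tsv(expr_file, col_types = readr::cols(
    gene_id = "c", fetal_median = "d", adult_median = "d",
    .default = "c"), progress = FALSE)

  dev_file <- run_stage("developmental-enrichment", {
    groups <- env$gene_classes[c("gene_id", "group")]
    bodies <- env$genes[c("gene_id", "chrom", "start", "end")]
    rows <- list()
    for (set in c("fetal_only", "adult_only")) {
      blocks <- if (set == "fetal_only") env$fetal_only else env$adult_only
      e <- developmental_group_enrichment(blocks, groups, bodies, env$genome)
      rows[[set]] <- dplyr::bind_cols(tibble(block_set = set), tidy(e))
    }
    f <- file.path(out_dir, "developmental_enrichment.tsv")
    readr::write_tsv(dplyr::bind_rows(rows), f)
    f
  })

  great_file <- run_stage("great", {
    terms <- read_terms(paths$terms)
    gr <- great_enrichment(env$fetal_only, env$genes, terms, env$genome)
    f <- file.path(out_dir, "great_fetal_only.tsv")
    readr::write_tsv(tidy(gr), f)
    f
  })
  env$great <- readr::read_tsv(great_file, col_types = readr::cols(
    term_id = "c", term_name = "c", .default = "d"), progress = FALSE)

  tabseq_out <- run_stage("tabseq", {
    sites <- tabseq_levels(read_tabseq(paths$tabseq))
    truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
    ivs <- as_tibble(truth$tabseq_intervals)
    rows <- list()
    for (sid in unique(sites$sample_id)) {
      ss <- sites[sites$sample_id == sid, ]
      im <- interval_mean(ss, ivs[c("interval_id", "chrom", "start", "end")])
      pk <- env$peaks[env$peaks$sample_id == sid, ]
      pos <- vapply(seq_len(nrow(im)), function(i) {
        iv <- im[i, c("chrom", "start", "end")]
        nrow(intersect_intervals(normalize_intervals(pk[c("chrom", "start",
                                                          "end")]),
                                 iv, env$genome)) > 0
      }, TRUE)
      rows[[sid]] <- dplyr::bind_cols(tibble(sample_id = sid), im,
                                      tibble(ngs_positive = pos))
    }
    grid <- dplyr::bind_rows(rows)
    f <- file.path(out_dir, "tabseq_intervals.tsv")
    readr::write_tsv(grid, f)
    conc <- tabseq_concordance(grid, an$call_threshold)
    list(file = f, concordance = conc)
  })

  mb <- function(b) interval_bp(b) / 1e6
  counts <- list(
    n_samples_fetal = sum(env$manifest$cohort == "fetal"),
    n_samples_adult = sum(env$manifest$cohort == "adult"),
    n_peaks_fetal = sum(env$peaks$cohort == "fetal"),
    n_peaks_adult = sum(env$peaks$cohort == "adult"),
    n_blocks_fetal = nrow(env$blocks$fetal),
    n_blocks_adult = nrow(env$blocks$adult),
    mb_blocks_fetal = mb(env$blocks$fetal),
    mb_blocks_adult = mb(env$blocks$adult),
    n_fetal_only = nrow(env$fetal_only),
    n_adult_only = nrow(env$adult_only),
    unique_peak_fraction_fetal = sharing$fetal$unique_fraction,
    unique_peak_fraction_adult = sharing$adult$unique_fraction,
    n_genes = nrow(env$genes),
    group_sizes = as.list(table(env$gene_classes$group)),
    top_term = env$great$term_id[1],
    tabseq = as.list(tabseq_out$concordance)
  )
  report <- list(
    seed = config$seed,
    parameters = config$analysis,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = list(
      simulate = paths[c("genome", "manifest", "genes", "expression",
                         "terms", "tabseq", "truth")],
      call_blocks = block_files,
      diff_blocks = diff_files,
      enrich = enrich_file,
      expr_groups = expr_file,
      developmental_enrichment = dev_file,
      great = great_file,
      tabseq = tabseq_out$file
    ),
    counts = counts
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
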