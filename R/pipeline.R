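#' Run configuration for the full analysis pipeline
#'
#' Every parameter has a default; the configuration round-trips through
#' JSON losslessly and is echoed into the run manifest.
#'
#' @param counts_file,lengths_file,design_file input paths (NULL to run on
#'   a simulated dataset instead; see \code{simulate}).
#' @param out_dir output directory.
#' @param seed integer seed used for every stochastic stage.
#' @param prior_count normalization prior count.
#' @param soft_power,min_module_size,merge_corr,cut_height network
#'   parameters (\code{soft_power = NULL} picks by the scale-free
#'   criterion).
#' @param n_perm_sets permutation sets for the pattern/median nulls.
#' @param alpha significance level for empirical p-values.
#' @param pairs_file optional paralog group TSV (group_id, gene_id);
#'   enables the pair stage.
#' @param responsive_file optional one-column file of responsive gene ids;
#'   enables the enrichment stage.
#' @param run_grn run the GRN stage on simulated two-species data.
#' @param simulate when no input files are given, parameters passed to
#'   \code{\link{sim_spec}} as a list.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(counts_file = NULL, lengths_file = NULL,
                       design_file = NULL, out_dir = "diffpat_out",
                       seed = 1L, prior_count = 0.1, soft_power = NULL,
                       min_module_size = 30L, merge_corr = 0.85,
                       cut_height = NULL, n_perm_sets = 1L, alpha = 0.01,
                       pairs_file = NULL, responsive_file = NULL,
                       run_grn = FALSE, simulate = list()) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full differential-pattern analysis
#'
#' Executes normalize -> modules -> kME -> pattern and median tests ->
#' (optional) paralog pair tests -> (optional) responsiveness enrichment,
#' writing result TSVs, a JSON manifest (parameters, seed, stage status)
#' and a plain-text log under \code{cfg$out_dir}. On stage failure the
#' partial outputs are preserved alongside a \code{FAILED} marker file and
#' the error is re-thrown.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return invisibly, a list with the main result objects and the manifest.
#' @export
run_full_analysis <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(cfg$out_dir, "run.log")
  manifest <- list(package = "diffpat",
                   version = as.character(utils::packageVersion("diffpat")),
                   seed = cfg$seed, alpha = cfg$alpha,
                   n_perm_sets = cfg$n_perm_sets, stages = list())
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                               "\n", file = log_file, append = TRUE)
  write_manifest <- function() jsonlite::write_json(
    manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- "FAILED"
    writeLines(paste(stage, conditionMessage(err)),
               file.path(cfg$out_dir, "FAILED"))
    write_manifest()
    stop(err)
  }
  run_stage <- function(stage, expr) {
    logline("stage", stage, "start")
    res <- tryCatch(expr, error = function(e) fail(stage, e))
    manifest$stages[[stage]] <<- "ok"
    logline("stage", stage, "done")
    res
  }
  results <- list()

  sim <- NULL
  if (is.null(cfg$counts_file)) {
    sim <- run_stage("simulate", {
      spec <- do.call(sim_spec, utils::modifyList(list(seed = cfg$seed),
                                                  cfg$simulate))
      simulate_timecourse(spec)
    })
    ct <- sim$counts; design <- sim$design
  } else {
    inp <- run_stage("read", {
      list(ct = read_count_table(cfg$counts_file, cfg$lengths_file),
           design = read_sample_design(cfg$design_file))
    })
    ct <- inp$ct; design <- inp$design
  }

  es <- run_stage("normalize", {
    es <- normalize_counts(ct, design, prior_count = cfg$prior_count)
    write_expression_set(es, file.path(cfg$out_dir, "expression_log2fpkm.tsv"))
    es
  })
  results$es <- es

  ms <- run_stage("modules", {
    ## module detection on the most variable genes keeps the network step
    ## tractable on large inputs; kME is still computed for every gene
    keep <- order(-apply(es$matrix, 1, stats::var))
    keep <- sort(utils::head(keep, 5000L))
    es_net <- expression_set(es$matrix[keep, , drop = FALSE], es$design,
                             es$norm_factors)
    beta <- cfg$soft_power %||% pick_soft_threshold(es_net)$power
    ms <- detect_modules(es_net, network_params(
      soft_power = beta, min_module_size = cfg$min_module_size,
      merge_corr = cfg$merge_corr, cut_height = cfg$cut_height))
    utils::write.table(
      data.frame(gene = names(ms$assignment), module = ms$assignment),
      file.path(cfg$out_dir, "modules.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(module = rownames(ms$eigengenes), ms$eigengenes,
                 check.names = FALSE),
      file.path(cfg$out_dir, "eigengenes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    ms
  })
  results$modules <- ms

  kme <- run_stage("kme", compute_kme(es, ms$eigengenes))
  results$kme <- kme

  pt <- run_stage("pattern_test",
                  pattern_test(kme, n_perm_sets = cfg$n_perm_sets,
                               seed = child_seed(cfg$seed, 11),
                               alpha = cfg$alpha))
  med <- run_stage("median_test", {
    medians <- median_profile(es)
    courses <- data.frame(
      treatment = sub("\\.[^.]*$", "", colnames(medians)),
      replicate = sub("^.*\\.", "", colnames(medians)),
      stringsAsFactors = FALSE)
    median_change_test(medians, courses, n_perm_sets = cfg$n_perm_sets,
                       seed = child_seed(cfg$seed, 12), alpha = cfg$alpha)
  })
  results$pattern <- pt
  results$median <- med
  run_stage("results_table", {
    tab <- merge(pt$table, med$table[c("gene", "t", "p")],
                 by = "gene", suffixes = c("_pattern", "_median"))
    names(tab)[names(tab) == "p_pattern"] <- "p_pattern"
    names(tab)[names(tab) == "p"] <- "p_median"
    tab$combined <- as.numeric(combined_score(pt, med)[tab$gene])
    utils::write.table(tab, file.path(cfg$out_dir, "pattern_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })

  if (!is.null(cfg$pairs_file)) {
    results$pairs <- run_stage("pairs", {
      groups <- utils::read.table(cfg$pairs_file, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
      pairs <- expand_pairs(groups, rownames(es$matrix))
      res <- pair_pattern_test(es, pairs, kme,
                               n_perm_sets = cfg$n_perm_sets,
                               seed = child_seed(cfg$seed, 13),
                               alpha = cfg$alpha)
      utils::write.table(res, file.path(cfg$out_dir, "pair_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
  } else manifest$stages$pairs <- "skipped"

  if (!is.null(cfg$responsive_file) && !is.null(results$pairs)) {
    results$enrichment <- run_stage("enrichment", {
      responsive <- readLines(cfg$responsive_file)
      subset <- results$pairs[results$pairs$significant_pattern, ]
      enr <- response_enrichment(subset, responsive, results$pairs,
                                 seed = child_seed(cfg$seed, 14))
      jsonlite::write_json(enr, file.path(cfg$out_dir, "enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
      enr
    })
  } else manifest$stages$enrichment <- "skipped"

  write_manifest()
  logline("run complete")
  invisible(c(results, list(manifest = manifest)))
}
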