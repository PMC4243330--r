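#' Pipeline configuration
#'
#' Everything needed for one reproducible run of the two-stage selection:
#' an input source (either file paths or a [sim_spec()]), optional QC,
#' the p-value adjustment mode and ladder, the kernel families and grids,
#' the cross-validation shape, the GA settings, and one master seed from
#' which every stage seed is derived deterministically (genotype stream =
#' seed, phenotype noise = seed + 1, CV = seed + 2, GA = seed + 3).
#'
#' @param genotypes_path,phenotype_path input files (with `dialect`), or
#' @param sim a [sim_spec()] for a fully synthetic run; exactly one input
#'   source must be given.
#' @param dialect genotype file dialect for [read_genotypes()].
#' @param qc a [qc_thresholds()] or `NULL` to skip QC.
#' @param use_adjusted group on Bonferroni-adjusted p-values?
#' @param ladder p-value thresholds ([ladder_real()] / [ladder_simulated()]).
#' @param families kernel families to evaluate.
#' @param grids hyperparameter grids ([default_grids()] form).
#' @param cv_folds,cv_repeats reported cross-validation shape.
#' @param tune_repeats CV repeats during grid search.
#' @param min_ga_size GA is skipped (with a logged reason) when the best
#'   group has at most this many SNPs: a small first-stage selection needs
#'   no second pruning.
#' @param ga population/generation/operator settings as a list understood by
#'   [ga_config()] (`svr_hyper` and `seed` are filled in by the pipeline).
#' @param seed master seed.
#' @param outdir output directory, or `NULL` to skip writing files.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes_path = NULL, phenotype_path = NULL,
                            sim = NULL, dialect = "csv", qc = NULL,
                            use_adjusted = FALSE, ladder = ladder_real(),
                            families = c("linear", "rbf", "puk"),
                            grids = default_grids(),
                            cv_folds = 10L, cv_repeats = 10L,
                            tune_repeats = 1L, min_ga_size = 10L,
                            ga = list(), seed = 1L, outdir = NULL) {
  has_files <- !is.null(genotypes_path)
  has_sim <- !is.null(sim)
  if (has_files == has_sim)
    stop("exactly one input source: genotype files or a sim_spec")
  if (has_sim) stopifnot(inherits(sim, "sim_spec"))
  structure(list(genotypes_path = genotypes_path,
                 phenotype_path = phenotype_path, sim = sim,
                 dialect = dialect, qc = qc, use_adjusted = use_adjusted,
                 ladder = ladder, families = families, grids = grids,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 tune_repeats = as.integer(tune_repeats),
                 min_ga_size = as.integer(min_ga_size), ga = ga,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

pipeline_log <- function(log, stage, msg) {
  entry <- sprintf("[%s] %s", stage, msg)
  message(entry)
  c(log, entry)
}

#' Run the full two-stage selection pipeline
#'
#' Orchestrates ingest (or simulation), optional quality control,
#' heterozygote imputation, monomorphic removal, Spearman ranking, nested
#' group construction, per-group SVR evaluation with tuned kernels,
#' best-group choice, the GA second selection (skipped with a logged reason
#' for small best groups), and before/after LD diagnostics. When
#' `config$outdir` is set, persists `stats.csv`, `groups.json`,
#' `group_evaluations.csv`, `ga_result.json`, `ld_before.csv`,
#' `ld_after.csv`, `run_log.txt` and `config.json`.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_result` with elements `stats`,
#'   `groups`, `evaluations` (long table), `best_group`, `best_family`,
#'   `ga` (a `ga_result` or `NULL`), `ga_skipped_reason`, `ld_before`,
#'   `ld_after`, `selected_snp_ids`, `log`, `seeds`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(genotype = config$seed, noise = config$seed + 1L,
                cv = config$seed + 2L, ga = config$seed + 3L)
  log <- character()

  # --- ingest -------------------------------------------------------------
  if (!is.null(config$sim)) {
    spec <- config$sim
    G <- simulate_genotypes(spec$n_subjects, spec$n_snps, spec$maf_low,
                            spec$maf_high, seed = seeds$genotype)
    y <- if (spec$model == "additive")
      simulate_phenotype_additive(G, spec, error_seed = seeds$noise)
    else simulate_phenotype_epistatic(G, spec, error_seed = seeds$noise)
    log <- pipeline_log(log, "ingest",
                        sprintf("simulated %d SNPs x %d subjects (%s model)",
                                spec$n_snps, spec$n_subjects, spec$model))
  } else {
    G <- read_genotypes(config$genotypes_path, config$dialect)
    y <- read_phenotype(config$phenotype_path)
    al <- align_phenotype(y, G)
    G <- al$genotypes; y <- al$phenotype
    log <- pipeline_log(log, "ingest",
                        sprintf("read %d SNPs x %d samples",
                                length(G$snp_ids), length(y)))
  }

  # --- qc / impute / monomorphic -----------------------------------------
  qc_report <- NULL
  if (!is.null(config$qc)) {
    res <- apply_qc(G, config$qc)
    G <- res$genotypes; qc_report <- res$report
    log <- pipeline_log(log, "qc", sprintf("%d SNPs retained, %d removed",
                                           res$report$n_retained,
                                           res$report$n_removed))
  }
  imp <- impute_missing_as_het(G)
  G <- imp$genotypes
  if (imp$n_imputed > 0)
    log <- pipeline_log(log, "impute",
                        sprintf("%d missing cells set to heterozygote",
                                imp$n_imputed))
  mono <- drop_monomorphic(G)
  G <- mono$genotypes
  if (length(mono$removed))
    log <- pipeline_log(log, "monomorphic",
                        sprintf("%d monomorphic SNPs removed",
                                length(mono$removed)))

  # --- stage 1: rank, group, evaluate ------------------------------------
  stats <- spearman_stats(G, y)
  groups <- build_groups(stats, config$ladder, config$use_adjusted)
  log <- pipeline_log(log, "rank",
                      sprintf("groups of sizes %s",
                              paste(groups$sizes, collapse = ", ")))
  ev <- evaluate_groups(G, y, groups, families = config$families,
                        grids = config$grids, k = config$cv_folds,
                        r = config$cv_repeats, tune_r = config$tune_repeats,
                        seed = seeds$cv)
  # best group judged on the PUK evaluations when present, else first family
  judge <- if ("puk" %in% config$families) "puk" else config$families[1]
  best <- select_best_group(groups, ev$evaluations[[judge]])
  log <- pipeline_log(log, "select",
                      sprintf("best group %d (p < %.3g): %d SNPs, mean r %.3f",
                              best$index, best$threshold,
                              length(best$snp_ids), best$cv$mean))

  # --- stage 2: GA --------------------------------------------------------
  ga_res <- NULL
  ga_skipped <- NULL
  selected <- best$snp_ids
  if (length(best$snp_ids) <= config$min_ga_size) {
    ga_skipped <- sprintf(
      "best group has %d SNP(s) (<= min_ga_size %d); second selection unnecessary",
      length(best$snp_ids), config$min_ga_size)
    log <- pipeline_log(log, "ga", paste("skipped:", ga_skipped))
  } else {
    ga_args <- config$ga
    ga_args$svr_hyper <- ev$hypers[[judge]][[best$index]]
    ga_args$seed <- seeds$ga
    ga_cfg <- do.call(ga_config, ga_args)
    ga_res <- ga_select(G$values[, best$snp_ids, drop = FALSE], y,
                        candidate_ids = best$snp_ids, config = ga_cfg)
    selected <- ga_res$selected_snp_ids
    log <- pipeline_log(log, "ga",
                        sprintf("%d of %d SNPs retained, CV-MSE %.4g",
                                length(selected), length(best$snp_ids),
                                ga_res$best_fitness))
  }

  # --- LD diagnostics -----------------------------------------------------
  ld_before <- if (length(best$snp_ids) >= 2)
    ld_r2_matrix(G, best$snp_ids) else NULL
  ld_after <- if (length(selected) >= 2) ld_r2_matrix(G, selected) else NULL

  result <- structure(list(stats = stats, groups = groups,
                           evaluations = ev$table, hypers = ev$hypers,
                           qc_report = qc_report,
                           best_group = best, best_family = judge,
                           ga = ga_res, ga_skipped_reason = ga_skipped,
                           ld_before = ld_before, ld_after = ld_after,
                           selected_snp_ids = selected,
                           log = log, seeds = seeds, config = config),
                      class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  utils::write.csv(result$stats, p("stats.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(thresholds = result$groups$thresholds,
         use_adjusted = result$groups$use_adjusted,
         members = result$groups$members),
    p("groups.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$evaluations, p("group_evaluations.csv"),
                   row.names = FALSE)
  if (!is.null(result$ga)) {
    jsonlite::write_json(
      list(selected_snp_ids = result$ga$selected_snp_ids,
           best_fitness = result$ga$best_fitness,
           trajectory = result$ga$trajectory,
           n_evaluations = result$ga$n_evaluations),
      p("ga_result.json"), auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(list(skipped = result$ga_skipped_reason),
                         p("ga_result.json"), auto_unbox = TRUE)
  }
  if (!is.null(result$ld_before))
    utils::write.csv(as.data.frame(unclass(result$ld_before)),
                     p("ld_before.csv"))
  if (!is.null(result$ld_after))
    utils::write.csv(as.data.frame(unclass(result$ld_after)), p("ld_after.csv"))
  writeLines(result$log, p("run_log.txt"))
  cfg <- result$config
  jsonlite::write_json(
    list(seed = cfg$seed, seeds = result$seeds, dialect = cfg$dialect,
         use_adjusted = cfg$use_adjusted, ladder = cfg$ladder,
         families = cfg$families, cv_folds = cfg$cv_folds,
         cv_repeats = cfg$cv_repeats, min_ga_size = cfg$min_ga_size,
         simulated = !is.null(cfg$sim)),
    p("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat("  best group:", x$best_group$index,
      sprintf("(p < %.3g, %d SNPs, mean r %.3f)\n", x$best_group$threshold,
              length(x$best_group$snp_ids), x$best_group$cv$mean))
  if (!is.null(x$ga))
    cat("  GA retained", length(x$selected_snp_ids), "SNPs\n")
  else cat("  GA skipped:", x$ga_skipped_reason, "\n")
  invisible(x)
}
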