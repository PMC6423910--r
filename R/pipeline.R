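#' Configuration for a full kit-comparison analysis run
#'
#' @param table a `count_table` (or path to a TSV/BIOM table).
#' @param design a [study_design()] (or path to a design TSV).
#' @param tree optional rooted `phylo` (or path to a newick file); enables
#'   the two UniFrac metrics.
#' @param normalize_depth depth to rarefy all samples to before analysis;
#'   `NULL` (default) uses the minimum sample total; `NA` skips
#'   normalization.
#' @param thresholds a [category_thresholds()].
#' @param filter_thresholds grid for [filter_sweep()].
#' @param anosim_permutations,permanova_permutations,indval_permutations
#'   permutation counts.
#' @param depths optional depth grid for [depth_sensitivity()]; `NULL`
#'   skips the stage.
#' @param seed master RNG seed; stage seeds are derived from it and logged.
#' @param out_dir optional directory; when given, all stage outputs are
#'   written as TSV plus a JSON run summary.
#' @return a `run_config` list.
#' @export
run_config <- function(table, design, tree = NULL,
                       normalize_depth = NULL,
                       thresholds = category_thresholds(),
                       filter_thresholds = c(1, 5, 10, 50, 100, 500),
                       anosim_permutations = 999,
                       permanova_permutations = 10000,
                       indval_permutations = 999,
                       depths = NULL,
                       seed = 1L,
                       out_dir = NULL) {
  if (is.character(table)) table <- read_count_table(table)
  if (is.character(design)) design <- read_design(design)
  if (is.character(tree)) tree <- read_tree(tree)
  cfg <- list(table = table, design = design, tree = tree,
              normalize_depth = normalize_depth, thresholds = thresholds,
              filter_thresholds = filter_thresholds,
              anosim_permutations = anosim_permutations,
              permanova_permutations = permanova_permutations,
              indval_permutations = indval_permutations,
              depths = depths, seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full kit-comparison analysis
#'
#' Stage order: rarefy to a common depth, classify OTUs into the six
#' abundance categories, alpha diversity (with Kruskal-Wallis kit tests),
#' the four dissimilarity matrices (two without a tree), ANOSIM and
#' PERMANOVA on Bray-Curtis for the whole community and for each category
#' subset, SIMPER with category roll-up, per-kit reproducibility (overall
#' and per category), optional depth sensitivity, indicator species
#' analysis, niche breadth, occurrence/Venn overlap, and the
#' low-abundance-filter sweep. All randomness derives from `config$seed`,
#' so a rerun with the same config reproduces every number.
#'
#' @param config a [run_config()].
#' @return named list of stage results (class `kitbias_run`), plus a
#'   `summary` element recording parameters, seeds and output files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- config$seed + seq_len(8)   # one sub-seed per stochastic stage
  table <- config$table
  design <- config$design

  if (!isTRUE(is.na(config$normalize_depth))) {
    depth <- if (is.null(config$normalize_depth)) min(sample_totals(table))
             else config$normalize_depth
    table <- subsample_reads(table, depth, seed = seeds[1])
  } else depth <- NA

  assignment <- classify_otus(table, config$thresholds)
  cat_summary <- category_summary(assignment, table)

  alpha <- alpha_diversity(table)
  alpha_tests <- lapply(c(observed_otus = "observed_otus", shannon = "shannon",
                          pielou = "pielou", chao1 = "chao1"),
                        function(col) {
    v <- stats::setNames(alpha[[col]], alpha$sample_id)
    v <- v[!is.na(v)]
    group_difference_test(v, design, "kruskal_wallis")
  })

  metrics <- if (is.null(config$tree)) c("bray", "jaccard") else
    c("bray", "jaccard", "uu", "wu")
  dms <- lapply(stats::setNames(metrics, metrics), function(mt)
    beta_diversity(table, mt, config$tree))

  run_tests <- function(dm, label) {
    list(label = label,
         anosim = anosim(dm, design, config$anosim_permutations, seed = seeds[2]),
         permanova = permanova(dm, design, config$permanova_permutations,
                               seed = seeds[3]))
  }
  cat_tests <- list(all = run_tests(dms$bray, "all"))
  for (cat in CATEGORY_LEVELS) {
    sub <- subset_by_category(table, assignment, cat)
    if (isTRUE(attr(sub, "empty"))) next
    if (length(attr(sub, "zero_samples")) > 0) next
    cat_tests[[cat]] <- run_tests(bray_counts(sub$counts), cat)
  }

  simper_res <- simper(table, design, assignment)
  repro <- reproducibility(dms$bray, design, assignment, table)

  depth_res <- if (!is.null(config$depths))
    depth_sensitivity(table, design, config$depths, seed = seeds[4]) else NULL

  indval <- indicator_species(table, design, config$indval_permutations,
                              seed = seeds[5])
  breadth <- niche_breadth(table, design)
  venn <- occurrence_venn(table, design)
  sweep_res <- filter_sweep(table, design, config$filter_thresholds)

  results <- list(table = table, assignment = assignment,
                  category_summary = cat_summary,
                  alpha = alpha, alpha_tests = alpha_tests,
                  distances = dms, category_tests = cat_tests,
                  simper = simper_res, reproducibility = repro,
                  depth_sensitivity = depth_res, indval = indval,
                  niche_breadth = breadth, venn = venn,
                  filter_sweep = sweep_res)
  results$summary <- list(
    n_otus = n_otus(table), n_samples = n_samples(table),
    normalize_depth = depth, metrics = metrics, seed = config$seed,
    stage_seeds = seeds,
    anosim_permutations = config$anosim_permutations,
    permanova_permutations = config$permanova_permutations,
    indval_permutations = config$indval_permutations)

  if (!is.null(config$out_dir)) {
    flat <- list(category_assignment = as.data.frame(assignment),
                 category_summary = cat_summary,
                 alpha_diversity = alpha,
                 simper_aggregate = simper_res$aggregate$otu,
                 reproducibility = repro,
                 indicator_species = as.data.frame(indval),
                 niche_breadth = breadth,
                 venn_regions = venn$regions,
                 occurrence_histogram = venn$occurrence_histogram,
                 filter_sweep = sweep_res$per_threshold,
                 filter_sweep_regressions = sweep_res$regressions)
    for (mt in metrics) flat[[paste0("distance_", mt)]] <- dms[[mt]]
    stat_rows <- do.call(rbind, lapply(cat_tests, function(x)
      data.frame(category = x$label,
                 anosim_R = x$anosim$observed, anosim_p = x$anosim$p_value,
                 permanova_R2 = x$permanova$R2, permanova_F = x$permanova$F,
                 permanova_p = x$permanova$p_value)))
    flat$permutation_tests <- stat_rows
    results$summary$files <- basename(write_results(flat, config$out_dir))
  }
  class(results) <- "kitbias_run"
  results
}

#' @export
print.kitbias_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("kitbias run: %d OTUs x %d samples (depth %s)\n",
              s$n_otus, s$n_samples, format(s$normalize_depth)))
  cat("ANOSIM (all, Bray-Curtis): ")
  print(x$category_tests$all$anosim)
  invisible(x)
}
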