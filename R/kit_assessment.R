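# Kit-comparison layer: replicate reproducibility (overall and per
# abundance category), sequencing-depth sensitivity, Levins niche breadth,
# occurrence/Venn overlap, and the low-abundance-filter sweep.

# Bray-Curtis on raw counts of a (possibly category-subset) matrix, with
# the denominator taken over the subset only; pairs where both samples
# have zero subset total get NA.
bray_counts <- function(m) {
  n <- ncol(m)
  d <- matrix(NA_real_, n, n, dimnames = list(colnames(m), colnames(m)))
  diag(d) <- 0
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    denom <- sum(m[, j] + m[, k])
    d[k, j] <- d[j, k] <- if (denom > 0) sum(abs(m[, j] - m[, k])) / denom else NA_real_
  }
  tag_dist(stats::as.dist(d), "bray_curtis_counts")
}

within_group_stats <- function(dm, design) {
  dd <- dist_design(dm, design, min_groups = 1)
  res <- lapply(levels(dd$g), function(lev) {
    sel <- dd$g[dd$i] == lev & dd$g[dd$j] == lev
    vals <- dd$d[sel]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0)
      return(data.frame(group = lev, n_pairs = 0L, mean_dissimilarity = NA_real_,
                        se = NA_real_, stringsAsFactors = FALSE))
    data.frame(group = lev, n_pairs = length(vals),
               mean_dissimilarity = mean(vals),
               se = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

between_group_mean <- function(dm, design) {
  dd <- dist_design(dm, design, min_groups = 2)
  between <- dd$g[dd$i] != dd$g[dd$j]
  mean(dd$d[between], na.rm = TRUE)
}

#' Replicate reproducibility of each extraction method
#'
#' For every group (kit), the mean and standard error of the pairwise
#' dissimilarities among its replicates: the lower the mean, the more
#' consistent the method. When an abundance-category assignment and the
#' count table are supplied, the same quantity is recomputed per category
#' on the category-subset counts (Bray-Curtis with the denominator over
#' the subset; no renormalization to the full community), alongside the
#' `"all"` row computed from `dm` itself. `similarity = 1 - mean
#' dissimilarity` is reported too, since "consistency" is quoted on both
#' orientations in the literature.
#'
#' @param dm a `dist` over samples (any metric).
#' @param design a [study_design()]; groups with a single replicate are
#'   skipped with a warning.
#' @param assignment optional `otu_categories` from [classify_otus()].
#' @param table the `count_table` behind `dm`; required with `assignment`.
#' @return data frame with columns `group`, `category`, `n_pairs`,
#'   `mean_dissimilarity`, `se`, `similarity`, `metric`.
#' @export
reproducibility <- function(dm, design, assignment = NULL, table = NULL) {
  singles <- names(which(base::table(design$group) < 2))
  if (length(singles) > 0) {
    warning("group(s) with a single replicate skipped: ",
            paste(singles, collapse = ", "))
    design <- design[!design$group %in% singles, , drop = FALSE]
    class(design) <- c("study_design", "data.frame")
    keep <- attr(dm, "Labels") %in% design$sample_id
    dm <- stats::as.dist(as.matrix(dm)[keep, keep])
  }
  metric <- attr(dm, "metric")
  if (is.null(metric)) metric <- "unknown"
  all_stats <- within_group_stats(dm, design)
  all_stats$category <- "all"
  out <- all_stats
  if (!is.null(assignment)) {
    if (is.null(table))
      stop("per-category reproducibility needs the count table", call. = FALSE)
    for (cat in CATEGORY_LEVELS) {
      sub <- subset_by_category(table, assignment, cat)
      if (isTRUE(attr(sub, "empty"))) next
      stats_cat <- within_group_stats(bray_counts(sub$counts), design)
      stats_cat$category <- cat
      out <- rbind(out, stats_cat)
    }
    if (metric != "bray_curtis")
      metric <- paste0(metric, "; categories: bray_curtis_counts")
  }
  out$similarity <- 1 - out$mean_dissimilarity
  out$metric <- metric
  rownames(out) <- NULL
  out[, c("group", "category", "n_pairs", "mean_dissimilarity", "se",
          "similarity", "metric")]
}

#' Effect of sequencing depth on reproducibility
#'
#' Subsamples every sample to each depth (without replacement, `draws`
#' independent times), recomputes within-kit reproducibility, and tests
#' the effect of depth on each kit's mean within-kit dissimilarity with a
#' one-way ANOVA across depths.
#'
#' @param table a `count_table`.
#' @param design a [study_design()].
#' @param depths vector of depths; the 16S convention is
#'   `c(10000, 20000, 30000, 40000)` and the 18S convention
#'   `seq(10000, 100000, by = 10000)`.
#' @param draws independent subsamples per depth.
#' @param seed RNG seed.
#' @param metric dissimilarity metric passed to [beta_diversity()].
#' @param tree optional tree for UniFrac metrics.
#' @return list with `per_draw` (data frame: depth, draw, group, mean
#'   within-group dissimilarity) and `anova` (per group: F and p across
#'   depths).
#' @export
depth_sensitivity <- function(table, design, depths = c(10000, 20000, 30000, 40000),
                              draws = 3, seed = NULL, metric = "bray",
                              tree = NULL) {
  m <- ct_matrix(table)
  if (max(depths) > min(colSums(m)))
    stop("largest depth exceeds the smallest sample total", call. = FALSE)
  if (draws < 1) stop("draws must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (d in sort(as.integer(depths))) for (b in seq_len(draws)) {
    sub <- subsample_reads(table, d)
    dm <- beta_diversity(sub, metric, tree)
    st <- within_group_stats(dm, design)
    rows[[length(rows) + 1]] <- data.frame(depth = d, draw = b,
                                           group = st$group,
                                           mean_dissimilarity = st$mean_dissimilarity,
                                           stringsAsFactors = FALSE)
  }
  per_draw <- do.call(rbind, rows)
  anova_rows <- lapply(unique(per_draw$group), function(gr) {
    sel <- per_draw[per_draw$group == gr, ]
    if (length(unique(sel$depth)) < 2 || any(base::table(sel$depth) < 2))
      return(data.frame(group = gr, F = NA_real_, p_value = NA_real_))
    fit <- summary(stats::aov(mean_dissimilarity ~ factor(depth), data = sel))[[1]]
    data.frame(group = gr, F = fit[["F value"]][1], p_value = fit[["Pr(>F)"]][1])
  })
  list(per_draw = per_draw, anova = do.call(rbind, anova_rows))
}

#' Levins niche breadth of each OTU across extraction kits
#'
#' `B_j = 1 / sum_i P_ij^2` where `P_ij` is OTU j's mean relative
#' abundance in kit i, normalized so the `P_ij` sum to 1 over kits.
#' B = 1 means the OTU is recovered by a single kit only; B = N means it
#' is spread evenly across all N kits. Occurrence is the number of kits
#' whose pooled replicates contain the OTU.
#'
#' @param table a `count_table`.
#' @param design a [study_design()].
#' @return data frame with columns `otu_id`, `breadth`, `occurrence`;
#'   OTUs absent everywhere are excluded.
#' @export
niche_breadth <- function(table, design) {
  m <- ct_matrix(table)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  rel <- relative_abundance(ct_matrix(table))[keep, , drop = FALSE]
  g <- droplevels(group_factor(design, colnames(m)))
  G <- stats::model.matrix(~ g - 1)
  meanrel <- sweep(rel %*% G, 2, colSums(G), "/")    # otus x groups
  P <- meanrel / rowSums(meanrel)
  pooled <- m %*% G
  data.frame(otu_id = rownames(m),
             breadth = as.numeric(1 / rowSums(P^2)),
             occurrence = as.integer(rowSums(pooled > 0)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-kit OTU occurrence: Venn region counts and occurrence histogram
#'
#' An OTU is detected by a kit when the pooled counts of the kit's
#' replicates are positive. Returns the per-kit OTU sets, the counts of
#' every intersection region of the Venn diagram (all `2^N - 1` non-empty
#' membership patterns), and the histogram of how many kits each OTU was
#' found in.
#'
#' @param table a `count_table`.
#' @param design a [study_design()] with >= 2 groups.
#' @return list with `sets` (named list of OTU id vectors), `regions`
#'   (data frame: membership pattern, count), `occurrence_histogram`
#'   (data frame: n_kits, n_otus).
#' @export
occurrence_venn <- function(table, design) {
  m <- ct_matrix(table)
  g <- droplevels(group_factor(design, colnames(m)))
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  G <- stats::model.matrix(~ g - 1)
  pres <- (m %*% G) > 0                       # otus x groups
  colnames(pres) <- levels(g)
  detected <- rowSums(pres) > 0
  pres <- pres[detected, , drop = FALSE]
  sets <- lapply(levels(g), function(lev) rownames(pres)[pres[, lev]])
  names(sets) <- levels(g)

  pattern <- apply(pres, 1, function(x) paste(levels(g)[x], collapse = "&"))
  all_patterns <- unlist(lapply(seq_len(nlevels(g)), function(k)
    utils::combn(levels(g), k, paste, collapse = "&")))
  counts <- base::table(factor(pattern, levels = all_patterns))
  regions <- data.frame(region = all_patterns, n_otus = as.integer(counts),
                        stringsAsFactors = FALSE)
  occ <- rowSums(pres)
  hist <- data.frame(n_kits = seq_len(nlevels(g)),
                     n_otus = as.integer(base::table(factor(occ, levels = seq_len(nlevels(g))))))
  list(sets = sets, regions = regions, occurrence_histogram = hist)
}

# per-group replicate overlap |intersection| / |union| of presence sets
replicate_overlap <- function(m, design) {
  g <- droplevels(group_factor(design, colnames(m)))
  vapply(levels(g), function(lev) {
    sub <- m[, g == lev, drop = FALSE] > 0
    uni <- rowSums(sub) > 0
    inter <- rowSums(sub) == ncol(sub)
    if (sum(uni) == 0) return(NA_real_)
    sum(inter) / sum(uni)
  }, numeric(1))
}

#' Low-abundance-filter sensitivity sweep
#'
#' For each threshold t, removes every OTU whose total count across all
#' samples is <= t, then recomputes (i) mean within-kit and between-kit
#' dissimilarity and (ii) each kit's replicate overlap (OTUs shared by all
#' replicates / OTUs in any replicate). Each response is regressed on
#' log10(t) by ordinary least squares. Thresholds that would remove every
#' OTU are flagged and excluded from the regressions.
#'
#' @param table a `count_table`.
#' @param design a [study_design()] with >= 2 groups.
#' @param thresholds positive integer thresholds (default
#'   `c(1, 5, 10, 50, 100, 500)`; pass 0 for the unfiltered reference
#'   point, which is excluded from the log-scale regression).
#' @param metric dissimilarity metric for [beta_diversity()].
#' @param tree optional tree for UniFrac metrics.
#' @return a `filter_sweep_result` list with `per_threshold` (data frame:
#'   threshold, OTUs retained, within/between mean dissimilarity, mean
#'   replicate overlap), `per_group_overlap`, and `regressions` (slope,
#'   intercept, R squared of each response vs log10 threshold).
#' @export
filter_sweep <- function(table, design, thresholds = c(1, 5, 10, 50, 100, 500),
                         metric = "bray", tree = NULL) {
  m <- ct_matrix(table)
  thresholds <- sort(unique(as.integer(thresholds)))
  if (any(thresholds < 0)) stop("thresholds must be >= 0", call. = FALSE)
  tot <- rowSums(m)
  rows <- list()
  overlap_rows <- list()
  for (t in thresholds) {
    keep <- tot > t
    if (!any(keep)) {
      rows[[length(rows) + 1]] <- data.frame(
        threshold = t, otus_retained = 0L, within_mean = NA_real_,
        between_mean = NA_real_, mean_overlap = NA_real_, empty = TRUE)
      next
    }
    sub <- m[keep, , drop = FALSE]
    if (any(colSums(sub) == 0)) {
      rows[[length(rows) + 1]] <- data.frame(
        threshold = t, otus_retained = sum(keep), within_mean = NA_real_,
        between_mean = NA_real_, mean_overlap = NA_real_, empty = TRUE)
      next
    }
    ct <- count_table(sub)
    dm <- beta_diversity(ct, metric, tree)
    w <- within_group_stats(dm, design)
    ov <- replicate_overlap(sub, design)
    rows[[length(rows) + 1]] <- data.frame(
      threshold = t, otus_retained = sum(keep),
      within_mean = stats::weighted.mean(w$mean_dissimilarity, w$n_pairs),
      between_mean = between_group_mean(dm, design),
      mean_overlap = mean(ov, na.rm = TRUE), empty = FALSE)
    overlap_rows[[length(overlap_rows) + 1]] <-
      data.frame(threshold = t, group = names(ov), overlap = as.numeric(ov),
                 stringsAsFactors = FALSE)
  }
  per_threshold <- do.call(rbind, rows)
  fit_one <- function(y) {
    ok <- !per_threshold$empty & per_threshold$threshold >= 1 & !is.na(y)
    if (sum(ok) < 2)
      return(data.frame(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_))
    f <- stats::lm(y[ok] ~ log10(per_threshold$threshold[ok]))
    data.frame(slope = stats::coef(f)[2], intercept = stats::coef(f)[1],
               r_squared = summary(f)$r.squared, row.names = NULL)
  }
  regressions <- rbind(
    cbind(response = "within_mean", fit_one(per_threshold$within_mean)),
    cbind(response = "between_mean", fit_one(per_threshold$between_mean)),
    cbind(response = "mean_overlap", fit_one(per_threshold$mean_overlap)))
  out <- list(per_threshold = per_threshold,
              per_group_overlap = do.call(rbind, overlap_rows),
              regressions = regressions, metric = metric)
  class(out) <- "filter_sweep_result"
  out
}

#' @export
print.filter_sweep_result <- function(x, ...) {
  cat("filter sweep (", x$metric, "):\n", sep = "")
  print(x$per_threshold, row.names = FALSE)
  invisible(x)
}
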