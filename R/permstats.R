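# Permutation statistics on distance matrices and count tables:
# ANOSIM, one-way PERMANOVA, SIMPER, indicator species analysis.
# All permutation p-values use the (hits + 1) / (n_permutations + 1)
# convention and are reproducible under a fixed seed.

# align a dist object with a design; returns list(d = vector of pairwise
# distances, g = group factor, i/j = pair indices, n = sample count)
dist_design <- function(dm, design, min_groups = 2) {
  labs <- attr(dm, "Labels")
  if (is.null(labs)) stop("distance matrix has no sample labels", call. = FALSE)
  g <- group_factor(design, labs)
  if (nlevels(droplevels(g)) < min_groups)
    stop("need at least ", min_groups, " groups", call. = FALSE)
  n <- length(labs)
  pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(d = as.vector(dm), g = droplevels(g),
       i = pairs[, "row"], j = pairs[, "col"], n = n, labels = labs)
}

perm_result <- function(statistic_name, observed, null, n_permutations, seed,
                        extra = list()) {
  p <- (sum(null >= observed) + 1) / (n_permutations + 1)
  out <- c(list(statistic_name = statistic_name, observed = observed,
                n_permutations = n_permutations, p_value = p,
                null_mean = mean(null), null_sd = stats::sd(null),
                seed = seed), extra)
  class(out) <- "permutation_test"
  out
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("%s = %.4f, p = %.4g (%d permutations)\n",
              x$statistic_name, x$observed, x$p_value, x$n_permutations))
  if (!is.null(x$R2)) cat(sprintf("R2 = %.4f, pseudo-F = %.4f\n", x$R2, x$F))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a distance matrix.
#' All `n(n-1)/2` pairwise distances are ranked (ties get midranks) and
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
#' so complete separation gives R = 1 and no separation gives R near 0.
#' Significance is assessed by permuting group labels across samples.
#'
#' @param dm a `dist` object over samples.
#' @param design a [study_design()]; at least two groups of two.
#' @param n_permutations number of random label permutations.
#' @param seed RNG seed for the permutations.
#' @return a `permutation_test` with fields `observed` (R),
#'   `p_value`, `null_mean`, `null_sd`.
#' @export
anosim <- function(dm, design, n_permutations = 999, seed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  dd <- dist_design(dm, design)
  if (any(table(dd$g) < 2)) stop("every group needs >= 2 samples", call. = FALSE)
  r <- rank(dd$d)
  denom <- dd$n * (dd$n - 1) / 4
  stat <- function(g) {
    within <- g[dd$i] == g[dd$j]
    (mean(r[!within]) - mean(r[within])) / denom
  }
  obs <- stat(dd$g)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(b) stat(sample(dd$g)),
                 numeric(1))
  perm_result("ANOSIM R", obs, null, n_permutations, seed)
}

#' One-way PERMANOVA (distance-based multivariate analysis of variance)
#'
#' Partitions the sum of squared dissimilarities:
#' `SS_total = (1/n) sum_{j<k} d_jk^2`,
#' `SS_within = sum_g (1/n_g) sum_{j<k in g} d_jk^2`,
#' `SS_among = SS_total - SS_within`, with pseudo-F
#' `(SS_among/(a-1)) / (SS_within/(n-a))` and `R2 = SS_among / SS_total`.
#' The p-value permutes group labels.
#'
#' @inheritParams anosim
#' @param n_permutations number of permutations (default 10,000).
#' @return a `permutation_test` with `observed` (pseudo-F) plus `R2`, `F`,
#'   and the sums of squares. If all distances are zero the result is
#'   flagged `degenerate` and carries no p-value.
#' @export
permanova <- function(dm, design, n_permutations = 10000, seed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  dd <- dist_design(dm, design)
  d2 <- dd$d^2
  n <- dd$n
  a <- nlevels(dd$g)
  ss_total <- sum(d2) / n
  n_g <- table(dd$g)
  within_ss <- function(g) {
    ss <- 0
    for (lev in levels(g)) {
      sel <- g[dd$i] == lev & g[dd$j] == lev
      ss <- ss + sum(d2[sel]) / n_g[[lev]]
    }
    ss
  }
  stat <- function(g) {
    ss_within <- within_ss(g)
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  }
  if (ss_total <= 0) {
    out <- list(statistic_name = "pseudo-F", observed = NA_real_,
                n_permutations = 0L, p_value = NA_real_, null_mean = NA_real_,
                null_sd = NA_real_, seed = seed, R2 = NA_real_, F = NA_real_,
                SS_total = ss_total, degenerate = TRUE)
    class(out) <- "permutation_test"
    return(out)
  }
  ss_within <- within_ss(dd$g)
  ss_among <- ss_total - ss_within
  obs <- stat(dd$g)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(b) stat(sample(dd$g)),
                 numeric(1))
  perm_result("pseudo-F", obs, null, n_permutations, seed,
              extra = list(F = obs, R2 = ss_among / ss_total,
                           SS_total = ss_total, SS_among = ss_among,
                           SS_within = ss_within, df_among = a - 1,
                           df_within = n - a, degenerate = FALSE))
}

# per-OTU Bray-Curtis contributions between two sample-index sets
simper_pair <- function(rel, idx1, idx2) {
  contrib <- numeric(nrow(rel))
  for (j in idx1) for (k in idx2) {
    denom <- sum(rel[, j] + rel[, k])
    contrib <- contrib + abs(rel[, j] - rel[, k]) / denom
  }
  contrib / (length(idx1) * length(idx2))
}

#' Similarity percentages (SIMPER)
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-OTU contributions: for each between-group sample pair (j, k),
#' OTU i contributes `|x_ij - x_ik| / sum_m (x_mj + x_mk)` (x = relative
#' abundances); contributions are averaged over all between-group pairs,
#' so they sum exactly to the mean between-group Bray-Curtis.
#'
#' With more than two groups the decomposition is run on every group pair
#' and an aggregate (the unweighted mean over pairs) is also reported.
#' When an abundance-category assignment is supplied, per-category
#' percentages (sums of member-OTU percentages) are added.
#'
#' @param table a `count_table`.
#' @param design a [study_design()] with at least two groups.
#' @param assignment optional `otu_categories` from [classify_otus()].
#' @return a `simper_result` list with elements `pairs` (per group pair: a
#'   data frame of per-OTU average contribution, percent and cumulative
#'   percent, sorted by contribution, plus the overall dissimilarity),
#'   `aggregate` (mean over pairs, same columns), and optionally
#'   `category_percent` per group pair and aggregate.
#' @export
simper <- function(table, design, assignment = NULL) {
  m <- ct_matrix(table)
  rel <- relative_abundance(m)
  g <- group_factor(design, colnames(m))
  levs <- levels(droplevels(g))
  if (length(levs) < 2) stop("SIMPER needs at least 2 groups", call. = FALSE)

  mk_df <- function(contrib) {
    ord <- order(contrib, decreasing = TRUE)
    total <- sum(contrib)
    pct <- if (total > 0) 100 * contrib / total else rep(0, length(contrib))
    data.frame(otu_id = rownames(m)[ord],
               average = contrib[ord],
               percent = pct[ord],
               cumulative_percent = cumsum(pct[ord]),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  pair_names <- character(0)
  pair_res <- list()
  contrib_mat <- NULL
  for (u in seq_along(levs)) for (v in seq_along(levs)) {
    if (v <= u) next
    contrib <- simper_pair(rel, which(g == levs[u]), which(g == levs[v]))
    nm <- paste(levs[u], levs[v], sep = "_vs_")
    pair_names <- c(pair_names, nm)
    pair_res[[nm]] <- list(otu = mk_df(contrib),
                           overall_dissimilarity = sum(contrib))
    contrib_mat <- cbind(contrib_mat, contrib)
  }
  agg <- rowMeans(contrib_mat)
  out <- list(pairs = pair_res,
              aggregate = list(otu = mk_df(agg),
                               overall_dissimilarity = sum(agg)))
  if (!is.null(assignment)) {
    cat_of <- stats::setNames(as.character(assignment$category), assignment$otu_id)
    roll <- function(df) {
      cc <- cat_of[df$otu_id]
      p <- tapply(df$percent, factor(cc, levels = CATEGORY_LEVELS), sum,
                  default = 0)
      data.frame(category = CATEGORY_LEVELS, percent = as.numeric(p),
                 row.names = NULL)
    }
    out$category_percent <- lapply(pair_res, function(x) roll(x$otu))
    out$category_percent$aggregate <- roll(out$aggregate$otu)
  }
  class(out) <- "simper_result"
  out
}

#' @export
print.simper_result <- function(x, ...) {
  cat(sprintf("SIMPER over %d group pair(s); aggregate mean between-group dissimilarity = %.4f\n",
              length(x$pairs), x$aggregate$overall_dissimilarity))
  print(utils::head(x$aggregate$otu, 5))
  invisible(x)
}

#' Indicator species analysis (IndVal)
#'
#' For OTU i and group g, specificity
#' `A_ig = mean relative abundance in g / sum_h mean relative abundance in h`
#' and fidelity `B_ig = fraction of g's samples containing the OTU`;
#' `IndVal_i = max_g A_ig * B_ig * 100`. Significance permutes whole
#' samples across groups (preserving within-sample OTU covariance) and an
#' OTU is flagged valid when IndVal > 50 and p < 0.05.
#'
#' @param table a `count_table`.
#' @param design a [study_design()] with >= 2 groups.
#' @param n_permutations label permutations for the p-value.
#' @param seed RNG seed.
#' @return data frame (class `indval_result`) with columns `otu_id`,
#'   `best_group`, `A`, `B`, `indval`, `p_value`, `valid`. OTUs absent
#'   everywhere are excluded.
#' @export
indicator_species <- function(table, design, n_permutations = 999, seed = NULL) {
  m <- ct_matrix(table)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  rel <- relative_abundance(ct_matrix(table))[keep, , drop = FALSE]
  g <- droplevels(group_factor(design, colnames(m)))
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  G <- stats::model.matrix(~ g - 1)           # samples x groups indicator
  n_g <- colSums(G)

  AB <- function(G) {
    meanrel <- sweep(rel %*% G, 2, n_g, "/")                # otus x groups
    A <- meanrel / rowSums(meanrel)
    B <- sweep((m > 0) %*% G, 2, n_g, "/")
    list(A = A, B = B, iv = A * B * 100)
  }
  ab <- AB(G)
  best <- max.col(ab$iv, ties.method = "first")
  pick <- cbind(seq_len(nrow(m)), best)
  obs <- ab$iv[pick]

  if (!is.null(seed)) set.seed(seed)
  exceed <- integer(nrow(m))
  for (b in seq_len(n_permutations)) {
    ivp <- AB(G[sample(nrow(G)), , drop = FALSE])$iv
    exceed <- exceed + (apply(ivp, 1, max) >= obs)
  }
  p <- (exceed + 1) / (n_permutations + 1)
  out <- data.frame(otu_id = rownames(m),
                    best_group = levels(g)[best],
                    A = ab$A[pick],
                    B = ab$B[pick],
                    indval = obs,
                    p_value = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$valid <- out$indval > 50 & out$p_value < 0.05
  class(out) <- c("indval_result", "data.frame")
  out
}

#' Classical group-difference tests on a per-sample quantity
#'
#' Thin dispatcher over the standard tests used to compare extraction
#' kits: Kruskal-Wallis ([stats::kruskal.test()]), Mann-Whitney U
#' ([stats::wilcox.test()], two groups only) and one-way ANOVA
#' ([stats::aov()]).
#'
#' @param values named numeric vector, one value per sample (names are
#'   sample ids), e.g. an alpha-diversity index.
#' @param design a [study_design()].
#' @param test one of `"kruskal_wallis"`, `"mann_whitney_u"`,
#'   `"one_way_anova"`.
#' @return list with `statistic`, `p_value`, `test`.
#' @export
group_difference_test <- function(values, design,
                                  test = c("kruskal_wallis", "mann_whitney_u",
                                           "one_way_anova")) {
  test <- match.arg(test)
  if (is.null(names(values))) stop("`values` must be named by sample id", call. = FALSE)
  g <- droplevels(group_factor(design, names(values)))
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (test == "kruskal_wallis") {
    ht <- stats::kruskal.test(values, g)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                test = test))
  }
  if (test == "mann_whitney_u") {
    if (nlevels(g) != 2) stop("Mann-Whitney U requires exactly 2 groups", call. = FALSE)
    ht <- stats::wilcox.test(values[g == levels(g)[1]],
                             values[g == levels(g)[2]], exact = FALSE)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                test = test))
  }
  if (any(table(g) < 2))
    stop("one-way ANOVA requires >= 2 observations per group", call. = FALSE)
  fit <- stats::aov(values ~ g)
  s <- summary(fit)[[1]]
  list(statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1], test = test)
}
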