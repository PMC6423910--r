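#' Alpha diversity per sample
#'
#' Observed richness, Shannon index (natural log), Pielou evenness and the
#' Chao1 richness estimator `S + F1*(F1-1) / (2*(F2+1))`, where F1 and F2
#' are the numbers of singleton and doubleton OTUs.
#'
#' @param table a `count_table`.
#' @return data frame with one row per sample and columns `sample_id`,
#'   `observed_otus`, `shannon`, `pielou`, `chao1`. Pielou evenness is `NA`
#'   for single-OTU samples (log richness is zero).
#' @examples
#' m <- matrix(c(4L, 2L, 1L, 1L), ncol = 1,
#'             dimnames = list(paste0("o", 1:4), "s1"))
#' alpha_diversity(count_table(m))
#' @export
alpha_diversity <- function(table) {
  m <- ct_matrix(table)
  res <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    x <- x[x > 0]
    p <- x / sum(x)
    s <- length(x)
    h <- -sum(p * log(p))
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    data.frame(sample_id = colnames(m)[j],
               observed_otus = s,
               shannon = h,
               pielou = if (s > 1) h / log(s) else NA_real_,
               chao1 = s + f1 * (f1 - 1) / (2 * (f2 + 1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Monte-Carlo rarefaction curves
#'
#' For each sample and each depth, subsamples the sequences without
#' replacement `iterations` times and records the mean and standard
#' deviation of observed richness.
#'
#' @param table a `count_table`.
#' @param depths increasing vector of subsampling depths; must not exceed
#'   any sample total.
#' @param iterations Monte-Carlo repetitions per depth.
#' @param seed optional RNG seed.
#' @return data frame with columns `sample_id`, `depth`, `mean_richness`,
#'   `sd_richness`.
#' @export
rarefaction_curve <- function(table, depths, iterations = 100, seed = NULL) {
  m <- ct_matrix(table)
  depths <- sort(as.integer(depths))
  tot <- colSums(m)
  if (max(depths) > min(tot))
    stop("depth ", max(depths), " exceeds the smallest sample total (", min(tot), ")",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (j in seq_len(ncol(m))) {
    pool <- rep.int(seq_len(nrow(m)), m[, j])
    for (d in depths) {
      rich <- vapply(seq_len(iterations), function(i) {
        if (d == length(pool)) return(sum(m[, j] > 0))
        length(unique(sample(pool, d, replace = FALSE)))
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = colnames(m)[j], depth = d,
        mean_richness = mean(rich), sd_richness = stats::sd(rich),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Expected richness under hypergeometric rarefaction
#'
#' Closed form `E[S_m] = sum_i (1 - C(N - N_i, m) / C(N, m))` for a single
#' sample; the analytic counterpart of [rarefaction_curve()].
#'
#' @param counts integer vector of OTU counts for one sample.
#' @param depth subsample size m.
#' @return expected number of OTUs observed.
#' @export
expected_richness <- function(counts, depth) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (depth > n) stop("depth exceeds sample total", call. = FALSE)
  # lchoose for numerical stability at survey-scale counts
  sum(1 - exp(lchoose(n - counts, depth) - lchoose(n, depth)))
}

# tag a dist object with the metric label used throughout the package
tag_dist <- function(d, metric) {
  attr(d, "method") <- metric
  attr(d, "metric") <- metric
  d
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(j,k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` computed on
#' per-sample relative abundances, making the distance invariant to
#' residual sequencing-depth differences.
#'
#' @param table a `count_table`.
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(table) {
  m <- ct_matrix(table)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  tag_dist(vegan::vegdist(t(relative_abundance(m)), method = "bray"),
           "bray_curtis")
}

#' Jaccard dissimilarity between samples (presence/absence)
#'
#' `d = 1 - |A intersect B| / |A union B|` on the OTU presence sets of the
#' two samples.
#'
#' @param table a `count_table`.
#' @return a `dist` object over samples.
#' @export
jaccard <- function(table) {
  m <- ct_matrix(table)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  tag_dist(vegan::vegdist(t(m > 0), method = "jaccard", binary = TRUE),
           "jaccard")
}

# per-edge descendant abundance fractions for every sample.
# Returns list(len = edge lengths, prop = edges x samples matrix of the
# fraction of each sample's sequences descending from the edge).
edge_proportions <- function(table, tree) {
  m <- ct_matrix(table)
  missing <- setdiff(rownames(m)[rowSums(m) > 0], tree$tip.label)
  if (length(missing) > 0)
    stop("OTUs absent from the tree: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
         call. = FALSE)
  extra <- setdiff(tree$tip.label, rownames(m))
  if (length(extra) > 0 && length(extra) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, setdiff(tree$tip.label, extra))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))

  rel <- relative_abundance(m)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  P <- matrix(0, nrow = ntip + nnode, ncol = ncol(rel))
  present <- intersect(tree$tip.label, rownames(rel))
  P[match(present, tree$tip.label), ] <- rel[present, , drop = FALSE]

  tr <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2]
    parent <- tr$edge[e, 1]
    P[parent, ] <- P[parent, ] + P[child, ]
  }
  list(len = tr$edge.length,
       prop = P[tr$edge[, 2], , drop = FALSE],
       samples = colnames(rel))
}

#' Unweighted UniFrac distance
#'
#' Fraction of total branch length leading exclusively to tips present in
#' one of the two samples:
#' `d = sum_b l_b * [branch unique to one sample] / sum_b l_b * [branch in either]`.
#' Tips present in the tree but absent from the table are pruned; OTUs with
#' nonzero counts that are missing from the tree are an error.
#'
#' @param table a `count_table`.
#' @param tree a rooted `phylo` object whose tips are OTU identifiers.
#' @return a `dist` object over samples.
#' @export
unweighted_unifrac <- function(table, tree) {
  ep <- edge_proportions(table, tree)
  pres <- ep$prop > 0
  n <- length(ep$samples)
  d <- matrix(0, n, n, dimnames = list(ep$samples, ep$samples))
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    union <- pres[, j] | pres[, k]
    uniq <- xor(pres[, j], pres[, k])
    denom <- sum(ep$len[union])
    d[k, j] <- d[j, k] <- if (denom == 0) 0 else sum(ep$len[uniq]) / denom
  }
  tag_dist(stats::as.dist(d), "unweighted_unifrac")
}

#' Weighted UniFrac distance
#'
#' Abundance-weighted branch-wise differences
#' `raw = sum_b l_b * |p_bA - p_bB|`, where `p_bX` is the fraction of
#' sample X's sequences descending from branch b. The normalized variant
#' (default) divides by `sum_b l_b * (p_bA + p_bB)` so the result lies in
#' \[0, 1\] and shares the scale of the other three metrics.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized divide by the maximum attainable value (default TRUE).
#' @return a `dist` object over samples.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  ep <- edge_proportions(table, tree)
  n <- length(ep$samples)
  d <- matrix(0, n, n, dimnames = list(ep$samples, ep$samples))
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    raw <- sum(ep$len * abs(ep$prop[, j] - ep$prop[, k]))
    if (normalized) {
      denom <- sum(ep$len * (ep$prop[, j] + ep$prop[, k]))
      raw <- if (denom == 0) 0 else raw / denom
    }
    d[k, j] <- d[j, k] <- raw
  }
  tag_dist(stats::as.dist(d),
           if (normalized) "weighted_unifrac" else "weighted_unifrac_raw")
}

#' Compute one of the four community dissimilarity matrices by name
#'
#' @param table a `count_table`.
#' @param metric `"bray"`, `"jaccard"`, `"uu"` (unweighted UniFrac) or
#'   `"wu"` (normalized weighted UniFrac).
#' @param tree rooted `phylo`, required for the UniFrac metrics.
#' @return a `dist` object over samples.
#' @export
beta_diversity <- function(table, metric = c("bray", "jaccard", "uu", "wu"),
                           tree = NULL) {
  metric <- match.arg(metric)
  if (metric %in% c("uu", "wu") && is.null(tree))
    stop("metric '", metric, "' requires a phylogenetic tree", call. = FALSE)
  switch(metric,
         bray = bray_curtis(table),
         jaccard = jaccard(table),
         uu = unweighted_unifrac(table, tree),
         wu = weighted_unifrac(table, tree))
}
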