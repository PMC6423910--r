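#' Abundance-category thresholds
#'
#' The classical definition of the abundant (>= 1% relative abundance) and
#' rare (< 0.01%) biosphere.
#'
#' @param abundant_cutoff relative abundance at or above which an OTU
#'   counts as abundant in a sample (default 0.01).
#' @param rare_cutoff relative abundance strictly below which an OTU counts
#'   as rare in a sample (default 1e-4).
#' @return a `category_thresholds` list.
#' @export
category_thresholds <- function(abundant_cutoff = 0.01, rare_cutoff = 1e-4) {
  if (!(rare_cutoff > 0 && rare_cutoff < abundant_cutoff && abundant_cutoff < 1))
    stop("need 0 < rare_cutoff < abundant_cutoff < 1", call. = FALSE)
  structure(list(abundant_cutoff = abundant_cutoff, rare_cutoff = rare_cutoff),
            class = "category_thresholds")
}

#' The six abundance category labels, from most to least abundant
#' @export
CATEGORY_LEVELS <- c("AT", "CAT", "CRAT", "MT", "CRT", "RT")

#' Classify OTUs into six exclusive abundance categories
#'
#' Each OTU is labelled from its relative abundances across all samples
#' analyzed together. With `anyA`/`allA` meaning the OTU reaches the
#' abundant cutoff in some/all samples and `anyR`/`allR` meaning it falls
#' below the rare cutoff in some/all samples:
#'
#' * `AT`  (always abundant): abundant in every sample.
#' * `CAT` (conditionally abundant): abundant in some samples, never rare.
#' * `CRAT` (conditionally rare and abundant): spans rare to abundant.
#' * `MT`  (moderate): never abundant, never rare.
#' * `CRT` (conditionally rare): rare in some samples, never abundant,
#'   not rare everywhere.
#' * `RT`  (always rare): rare in every sample.
#'
#' Boundary convention: "abundant" is `>= abundant_cutoff` and "rare" is
#' strictly `< rare_cutoff`, so an OTU sitting exactly at the rare cutoff
#' is not rare; this single convention makes the six categories an
#' exhaustive, exclusive partition. A zero count is relative abundance 0
#' and therefore rare, so an OTU absent from any sample can only be CRT,
#' CRAT or RT. OTUs with zero total count across all samples are excluded
#' with a warning and reported in the `excluded` attribute.
#'
#' @param table a `count_table`.
#' @param thresholds a [category_thresholds()].
#' @return data frame (class `otu_categories`) with columns `otu_id`,
#'   `category` (factor with levels [CATEGORY_LEVELS]), `min_rel_abund`,
#'   `max_rel_abund`; excluded all-zero OTUs in `attr(, "excluded")`.
#' @export
classify_otus <- function(table, thresholds = category_thresholds()) {
  m <- ct_matrix(table)
  tot <- rowSums(m)
  excluded <- rownames(m)[tot == 0]
  if (length(excluded) > 0) {
    warning(length(excluded), " OTU(s) with zero total count excluded from classification")
    m <- m[tot > 0, , drop = FALSE]
  }
  rel <- sweep(m, 2, colSums(ct_matrix(table)), "/")
  rmin <- apply(rel, 1, min)
  rmax <- apply(rel, 1, max)
  ab <- thresholds$abundant_cutoff
  ra <- thresholds$rare_cutoff
  cat <- classify_from_range(rmin, rmax, ab, ra)
  out <- data.frame(otu_id = rownames(m),
                    category = factor(cat, levels = CATEGORY_LEVELS),
                    min_rel_abund = rmin, max_rel_abund = rmax,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("otu_categories", "data.frame")
  attr(out, "thresholds") <- thresholds
  attr(out, "excluded") <- excluded
  out
}

# label from the per-OTU min/max relative abundance; the 2x2x2 flag space
# (anyA, anyR with allA/allR refinements) collapses to 6 reachable labels
classify_from_range <- function(rmin, rmax, abundant_cutoff, rare_cutoff) {
  anyA <- rmax >= abundant_cutoff
  allA <- rmin >= abundant_cutoff
  anyR <- rmin < rare_cutoff
  allR <- rmax < rare_cutoff
  ifelse(allA, "AT",
  ifelse(anyA & anyR, "CRAT",
  ifelse(anyA, "CAT",
  ifelse(allR, "RT",
  ifelse(anyR, "CRT", "MT")))))
}

#' Per-category OTU and sequence summaries
#'
#' @param assignment an `otu_categories` result from [classify_otus()].
#' @param table the `count_table` the assignment was derived from.
#' @return data frame with, per category: number of OTUs, percent of OTUs,
#'   total sequences, percent of sequences. Percent columns each sum
#'   to 100.
#' @export
category_summary <- function(assignment, table) {
  m <- ct_matrix(table)
  if (!all(assignment$otu_id %in% rownames(m)))
    stop("assignment contains OTUs absent from the table", call. = FALSE)
  seqs <- rowSums(m)[assignment$otu_id]
  n_otu <- tapply(assignment$otu_id, assignment$category, length, default = 0)
  n_seq <- tapply(seqs, assignment$category, sum, default = 0)
  data.frame(category = factor(CATEGORY_LEVELS, levels = CATEGORY_LEVELS),
             n_otus = as.integer(n_otu[CATEGORY_LEVELS]),
             otu_percent = 100 * n_otu[CATEGORY_LEVELS] / sum(n_otu),
             n_sequences = as.numeric(n_seq[CATEGORY_LEVELS]),
             sequence_percent = 100 * n_seq[CATEGORY_LEVELS] / sum(n_seq),
             row.names = NULL)
}

#' Restrict a count table to the OTUs of one abundance category
#'
#' @param table a `count_table`.
#' @param assignment an `otu_categories` from [classify_otus()].
#' @param category one of [CATEGORY_LEVELS].
#' @return the subset table. When the category holds no OTUs an empty
#'   matrix is returned with attribute `empty = TRUE` (downstream
#'   statistics refuse it); samples whose subset total is zero are listed
#'   in attribute `zero_samples`. The subset is returned as a plain matrix
#'   wrapper (class `count_subset`) because columns may legitimately sum
#'   to zero within a category.
#' @export
subset_by_category <- function(table, assignment, category) {
  category <- match.arg(category, CATEGORY_LEVELS)
  m <- ct_matrix(table)
  keep <- assignment$otu_id[assignment$category == category]
  sub <- m[rownames(m) %in% keep, , drop = FALSE]
  out <- structure(list(counts = sub), class = c("count_subset", "count_table"))
  attr(out, "category") <- category
  attr(out, "empty") <- nrow(sub) == 0
  attr(out, "zero_samples") <- colnames(sub)[colSums(sub) == 0]
  out
}

#' @export
print.count_subset <- function(x, ...) {
  cat(sprintf("count_subset [%s]: %d OTUs x %d samples%s\n",
              attr(x, "category"), nrow(x$counts), ncol(x$counts),
              if (isTRUE(attr(x, "empty"))) " (empty)" else ""))
  invisible(x)
}
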