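#' Construct and validate an OTU count table
#'
#' A `count_table` is an OTU-by-sample matrix of non-negative integer
#' sequence counts with unique OTU row names and unique sample column
#' names. All downstream analyses (abundance categories, diversity,
#' permutation statistics) operate on this container or on relative
#' abundances derived from it.
#'
#' Counts must be whole numbers: the analyses are defined on sequence
#' counts, and rarefaction and low-abundance filter thresholds are
#' meaningless on real-valued data. Samples with zero total are rejected
#' because their relative abundances are undefined.
#'
#' @param counts numeric matrix of non-negative whole numbers; rows are
#'   OTUs, columns are samples, both with unique dimnames.
#' @return A `count_table` object.
#' @examples
#' m <- matrix(c(5L, 3L, 0L, 0L, 2L, 7L), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' ct <- count_table(m)
#' sample_totals(ct)
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs OTU row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count at OTU '%s', sample '%s': %s (must be a non-negative integer)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])),
         call. = FALSE)
  }
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("samples with zero total counts: ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  storage.mode(counts) <- "double"
  structure(list(counts = counts), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d OTUs x %d samples\n", n_otus(x), n_samples(x)))
  cat(sprintf("sample totals: %s\n",
              paste(format(sample_totals(x), big.mark = ","), collapse = " ")))
  invisible(x)
}

#' @export
as.matrix.count_table <- function(x, ...) x$counts

#' @rdname count_table
#' @param x a `count_table`.
#' @export
otu_ids <- function(x) rownames(ct_matrix(x))

#' @rdname count_table
#' @export
sample_ids <- function(x) colnames(ct_matrix(x))

#' @rdname count_table
#' @export
n_otus <- function(x) nrow(ct_matrix(x))

#' @rdname count_table
#' @export
n_samples <- function(x) ncol(ct_matrix(x))

#' @rdname count_table
#' @export
sample_totals <- function(x) colSums(ct_matrix(x))

# accept count_table or plain matrix everywhere
ct_matrix <- function(x) {
  if (inherits(x, "count_table")) return(x$counts)
  if (is.matrix(x)) return(count_table(x)$counts)
  stop("expected a count_table or a matrix", call. = FALSE)
}

#' Per-sample relative abundances
#'
#' Divides each sample column by its total so that every column sums to 1.
#'
#' @param table a `count_table` or OTU-by-sample matrix.
#' @return numeric matrix of relative abundances with the same dimnames.
#' @export
relative_abundance <- function(table) {
  m <- ct_matrix(table)
  sweep(m, 2, colSums(m), "/")
}

#' Read an OTU count table from a file
#'
#' Reads either a tab-separated OTU-by-sample table (first column holds OTU
#' identifiers, conventionally headed `#OTU_ID`, remaining columns are
#' samples) or a BIOM 1.0 JSON table (requires the `biomformat` package).
#' Row and column order of the input are preserved.
#'
#' @param path file path.
#' @param format `"tsv"`, `"biom"`, or `"auto"` (by file extension;
#'   `.biom`/`.json` is read as BIOM, anything else as TSV).
#' @return a validated [count_table()].
#' @export
read_count_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE)) "biom" else "tsv"
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(count_table(m))
  }
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1]))
    stop("duplicate sample identifiers in header: ",
         paste(unique(header[-1][duplicated(header[-1])]), collapse = ", "),
         call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  if (ncol(df) < 2) stop("count table needs an identifier column and at least one sample", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  colnames(m) <- header[-1]
  rownames(m) <- as.character(df[[1]])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))), arr.ind = TRUE)
    stop(sprintf("non-numeric count at OTU '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  count_table(m)
}

#' Write an OTU count table to TSV
#'
#' @param table a `count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  m <- ct_matrix(table)
  df <- data.frame("#OTU_ID" = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a study design (sample-to-kit assignment)
#'
#' Maps each sample to an extraction-method group (kit) and a replicate
#' label. Group order follows first appearance and is used for reporting.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group character vector of group (kit) labels, same length.
#' @param replicate character or integer vector of replicate labels.
#' @return a `study_design` data frame.
#' @export
study_design <- function(sample_id, group, replicate) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  if (length(group) != length(sample_id) || length(replicate) != length(sample_id))
    stop("sample_id, group and replicate must have equal length", call. = FALSE)
  d <- data.frame(sample_id = sample_id,
                  group = as.character(group),
                  replicate = as.character(replicate),
                  stringsAsFactors = FALSE)
  class(d) <- c("study_design", "data.frame")
  d
}

#' @export
print.study_design <- function(x, ...) {
  g <- design_groups(x)
  cat(sprintf("study_design: %d samples, %d groups (%s)\n",
              nrow(x), length(g), paste(g, collapse = ", ")))
  invisible(x)
}

#' Group labels of a study design, in first-appearance order
#' @param design a `study_design`.
#' @export
design_groups <- function(design) unique(design$group)

# group factor aligned to a vector of sample ids; errors on missing samples
group_factor <- function(design, sample_ids) {
  idx <- match(sample_ids, design$sample_id)
  if (anyNA(idx))
    stop("samples missing from design: ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  factor(design$group[idx], levels = design_groups(design))
}

#' Read a study design from a TSV file
#'
#' Expects a header line `sample_id<TAB>group<TAB>replicate`.
#'
#' @param path file path.
#' @return a [study_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "group", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("design file missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  study_design(df$sample_id, df$group, df$replicate)
}

#' Write a study design to TSV
#' @param design a `study_design`.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree in newick format
#'
#' Wraps [ape::read.tree()]. Missing branch lengths are treated as zero; an
#' unrooted (basal multifurcation) tree is accepted with a warning and
#' treated as rooted at its given basal node, which is how UniFrac consumes
#' it.
#'
#' @param path newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("tree file missing or empty: ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("cannot parse newick file: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("cannot parse newick file: ", path, call. = FALSE)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("tree has duplicate tip labels", call. = FALSE)
  if (!ape::is.rooted(tr))
    warning("tree is unrooted (basal multifurcation); treating the basal node as the root")
  tr
}

#' Write a distance matrix as a square TSV table
#' @param dm a `dist` object or square matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV distance matrix written by [write_distance_matrix()]
#' @param path file path.
#' @return a `dist` object.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stats::as.dist(m)
}

#' Write a set of result objects to a directory
#'
#' Writes every data-frame-like or distance-matrix result as TSV and a
#' machine-readable JSON run summary listing the files produced.
#'
#' @param results named list; elements may be data frames, matrices, `dist`
#'   objects, or atomic vectors (stored in the summary only).
#' @param out_dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  stopifnot(is.list(results))
  files <- character(0)
  scalars <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    if (inherits(x, "dist")) {
      write_distance_matrix(x, path)
      files <- c(files, path)
    } else if (inherits(x, "count_table")) {
      write_count_table(x, path)
      files <- c(files, path)
    } else if (is.data.frame(x) || is.matrix(x)) {
      utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, path)
    } else {
      scalars[[nm]] <- x
    }
  }
  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(list(files = basename(files), values = scalars,
                            written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, summary_path))
}
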