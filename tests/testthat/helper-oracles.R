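# Independent oracle implementations used to verify the package's
# permutation statistics, UniFrac and classification code. These are
# deliberately slow, literal transcriptions of the definitions and share
# no code with the implementations they check.

# small random count table with unique ids
random_table <- function(n_otu, n_sample, lambda = 5, zero_frac = 0.3) {
  m <- matrix(rpois(n_otu * n_sample, lambda), nrow = n_otu,
              dimnames = list(paste0("o", seq_len(n_otu)),
                              paste0("s", seq_len(n_sample))))
  m[runif(length(m)) < zero_frac] <- 0L
  # make sure no sample is empty
  for (j in seq_len(n_sample)) if (sum(m[, j]) == 0) m[1, j] <- 1L
  count_table(m)
}

design_for <- function(sizes, labels = LETTERS[seq_along(sizes)]) {
  study_design(sample_id = paste0("s", seq_len(sum(sizes))),
               group = rep(labels, sizes),
               replicate = unlist(lapply(sizes, seq_len)))
}

# --- exhaustive ANOSIM oracle ------------------------------------------

# all distinct assignments of a multiset of labels to positions
all_label_assignments <- function(labels) {
  labels <- as.character(labels)
  recurse <- function(remaining) {
    if (length(remaining) == 0) return(list(character(0)))
    out <- list()
    for (lab in unique(remaining)) {
      rest <- remaining[-match(lab, remaining)]
      for (tail in recurse(rest)) out[[length(out) + 1]] <- c(lab, tail)
    }
    out
  }
  recurse(sort(labels))
}

# literal ANOSIM R from a distance matrix and a label vector
anosim_R_oracle <- function(dm, labels) {
  M <- as.matrix(dm)
  n <- nrow(M)
  d <- c()
  within <- c()
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    d <- c(d, M[j, k])
    within <- c(within, labels[j] == labels[k])
  }
  r <- rank(d)
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

# exhaustive permutation p-value: share of assignments with R >= observed
anosim_exhaustive_p <- function(dm, labels) {
  obs <- anosim_R_oracle(dm, labels)
  assigns <- all_label_assignments(labels)
  rs <- vapply(assigns, function(a) anosim_R_oracle(dm, a), numeric(1))
  mean(rs >= obs - 1e-12)
}

# --- brute-force SIMPER oracle -----------------------------------------

simper_oracle <- function(table, design, g1, g2) {
  m <- as.matrix(table)
  rel <- sweep(m, 2, colSums(m), "/")
  gg <- design$group[match(colnames(m), design$sample_id)]
  idx1 <- which(gg == g1); idx2 <- which(gg == g2)
  contrib <- rep(0, nrow(m))
  np <- 0
  for (j in idx1) for (k in idx2) {
    np <- np + 1
    denom <- 0
    for (i in seq_len(nrow(m))) denom <- denom + rel[i, j] + rel[i, k]
    for (i in seq_len(nrow(m)))
      contrib[i] <- contrib[i] + abs(rel[i, j] - rel[i, k]) / denom
  }
  setNames(contrib / np, rownames(m))
}

# --- brute-force UniFrac oracle ----------------------------------------

# tips descending from the child node of each edge, by naive recursion
edge_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) desc(tree$edge[e, 2]))
}

unifrac_oracle <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  m <- as.matrix(table)
  rel <- sweep(m, 2, colSums(m), "/")
  sets <- edge_tip_sets(tree)
  len <- tree$edge.length
  n <- ncol(m)
  D <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (weighted) {
      num <- denom <- 0
      for (e in seq_along(sets)) {
        pa <- sum(rel[sets[[e]], a]); pb <- sum(rel[sets[[e]], b])
        num <- num + len[e] * abs(pa - pb)
        denom <- denom + len[e] * (pa + pb)
      }
      D[b, a] <- D[a, b] <- if (normalized) {
        if (denom == 0) 0 else num / denom
      } else num
    } else {
      shared <- uniq <- 0
      for (e in seq_along(sets)) {
        ina <- any(m[sets[[e]], a] > 0); inb <- any(m[sets[[e]], b] > 0)
        if (ina && inb) shared <- shared + len[e]
        else if (ina || inb) uniq <- uniq + len[e]
      }
      tot <- shared + uniq
      D[b, a] <- D[a, b] <- if (tot == 0) 0 else uniq / tot
    }
  }
  as.dist(D)
}

# --- abundance-category truth table ------------------------------------

# expected label from the four flags, spelled out case by case
label_from_flags <- function(anyA, allA, anyR, allR) {
  if (allA) "AT"
  else if (anyA && anyR) "CRAT"
  else if (anyA && !anyR) "CAT"
  else if (allR) "RT"
  else if (anyR) "CRT"
  else "MT"
}
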