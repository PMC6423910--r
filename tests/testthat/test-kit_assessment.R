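test_that("reproducibility summarizes within-kit pairwise dissimilarities", {
  # three replicates at hand-set pairwise distances 0.1, 0.2, 0.3
  M <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  M[2, 1] <- M[1, 2] <- 0.1
  M[3, 1] <- M[1, 3] <- 0.2
  M[3, 2] <- M[2, 3] <- 0.3
  d <- design_for(3, labels = "K")
  res <- reproducibility(as.dist(M), d)
  expect_equal(res$mean_dissimilarity, 0.2)
  expect_equal(res$se, sd(c(0.1, 0.2, 0.3)) / sqrt(3), tolerance = 1e-9)
  expect_equal(res$n_pairs, 3L)
  expect_equal(res$similarity, 0.8)

  # identical replicates are perfectly reproducible
  m <- matrix(rep(c(5L, 3L, 2L), 3), 3, dimnames = list(letters[1:3], paste0("s", 1:3)))
  res0 <- reproducibility(bray_curtis(count_table(m)), d)
  expect_equal(res0$mean_dissimilarity, 0)
  expect_equal(res0$se, 0)

  # a single-replicate group is skipped with a warning
  d2 <- design_for(c(2, 1))
  M4 <- as.matrix(dist(1:3)); dimnames(M4) <- list(paste0("s", 1:3), paste0("s", 1:3))
  expect_warning(r2 <- reproducibility(as.dist(M4), d2), "single replicate")
  expect_identical(r2$group, "A")
})

test_that("per-category reproducibility shows larger variation for rare than abundant taxa under rare-biased kits", {
  sim <- simulate_tables(simulation_config(n_otus = 800, depth = 20000, seed = 31))
  asg <- suppressWarnings(classify_otus(sim$table))
  dm <- bray_curtis(sim$table)
  res <- reproducibility(dm, sim$design, asg, sim$table)
  expect_true(all(res$mean_dissimilarity >= 0 & res$mean_dissimilarity <= 1, na.rm = TRUE))
  # "all" rows equal the category-free computation
  plain <- reproducibility(dm, sim$design)
  expect_equal(res$mean_dissimilarity[res$category == "all"],
               plain$mean_dissimilarity)
  # rare categories less consistent than the abundant head, kit by kit
  wide <- res[res$category %in% c("AT", "CRT"), ]
  for (g in unique(wide$group)) {
    at <- wide$mean_dissimilarity[wide$group == g & wide$category == "AT"]
    crt <- wide$mean_dissimilarity[wide$group == g & wide$category == "CRT"]
    if (length(at) == 1 && length(crt) == 1) expect_gt(crt, at)
  }
})

test_that("depth sensitivity at full depth with one draw equals plain reproducibility", {
  sim <- simulate_tables(simulation_config(n_otus = 120, depth = 2000, seed = 3))
  full <- sum(as.matrix(sim$table)[, 1])
  ds <- depth_sensitivity(sim$table, sim$design, depths = full, draws = 1, seed = 1)
  plain <- reproducibility(bray_curtis(sim$table), sim$design)
  expect_equal(ds$per_draw$mean_dissimilarity, plain$mean_dissimilarity,
               tolerance = 1e-12)
  expect_true(all(is.na(ds$anova$F)))   # a single depth has no contrast

  expect_error(depth_sensitivity(sim$table, sim$design, depths = full + 1),
               "exceeds")
})

test_that("depth sensitivity spans a grid and runs its ANOVA", {
  sim <- simulate_tables(simulation_config(n_otus = 150, depth = 4000, seed = 17))
  ds <- depth_sensitivity(sim$table, sim$design, depths = c(500, 2000, 4000),
                          draws = 3, seed = 2)
  expect_equal(sort(unique(ds$per_draw$depth)), c(500, 2000, 4000))
  expect_equal(nrow(ds$anova), 5L)
  expect_true(all(ds$anova$p_value >= 0 & ds$anova$p_value <= 1, na.rm = TRUE))
})

test_that("niche breadth hits its closed-form anchors", {
  # OTU in one kit only -> B = 1; uniform across 5 kits -> B = 5;
  # present equally in 2 of 5 kits -> B = 2. A background OTU equalizes
  # the sample totals so relative abundances are proportional to counts.
  m <- matrix(0L, 4, 15, dimnames = list(c("one", "uniform", "two", "bg"),
                                         paste0("s", 1:15)))
  m["one", 1:3] <- 10L
  m["uniform", ] <- 10L
  m["two", 1:6] <- 10L
  m["bg", ] <- 1000L - colSums(m)
  ct <- count_table(m)
  d <- design_for(c(3, 3, 3, 3, 3))
  nb <- niche_breadth(ct, d)
  expect_equal(nb$breadth[nb$otu_id == "one"], 1, tolerance = 1e-9)
  expect_equal(nb$breadth[nb$otu_id == "uniform"], 5, tolerance = 1e-9)
  expect_equal(nb$breadth[nb$otu_id == "two"], 2, tolerance = 1e-9)
  expect_equal(nb$occurrence[nb$otu_id == "one"], 1L)
  expect_equal(nb$occurrence[nb$otu_id == "uniform"], 5L)
  expect_true(all(nb$breadth >= 1 - 1e-9 & nb$breadth <= 5 + 1e-9))
})

test_that("niche breadth is invariant to scaling one OTU's counts", {
  sim <- simulate_tables(simulation_config(n_otus = 80, depth = 2000, seed = 41))
  nb1 <- niche_breadth(sim$table, sim$design)
  m <- as.matrix(sim$table)
  # pick a low-abundance OTU found in several kits: scaling it leaves the
  # per-sample totals (the only non-cancelling term) essentially unchanged
  tot <- rowSums(m)[nb1$otu_id]
  cand <- nb1$otu_id[nb1$occurrence >= 3 & tot <= quantile(tot, 0.2)]
  target <- cand[1]
  m[target, ] <- m[target, ] * 3
  nb2 <- niche_breadth(count_table(m), sim$design)
  b1 <- nb1$breadth[nb1$otu_id == target]
  b2 <- nb2$breadth[nb2$otu_id == target]
  expect_equal(b1, b2, tolerance = 0.01)
})

test_that("occurrence/Venn regions match brute-force set algebra", {
  set.seed(52)
  ct <- random_table(40, 6, lambda = 2, zero_frac = 0.5)
  d <- design_for(c(2, 2, 2))
  v <- occurrence_venn(ct, d)
  expect_equal(nrow(v$regions), 2^3 - 1)
  m <- as.matrix(ct)
  pres <- cbind(A = rowSums(m[, 1:2]) > 0, B = rowSums(m[, 3:4]) > 0,
                C = rowSums(m[, 5:6]) > 0)
  detected <- rowSums(pres) > 0
  expect_equal(sum(v$regions$n_otus), sum(detected))
  # every region against direct enumeration
  for (r in seq_len(nrow(v$regions))) {
    members <- strsplit(v$regions$region[r], "&")[[1]]
    inside <- rowSums(pres[, members, drop = FALSE]) == length(members) &
      rowSums(pres[, setdiff(colnames(pres), members), drop = FALSE]) == 0
    expect_equal(v$regions$n_otus[r], sum(inside))
  }
  expect_equal(sum(v$occurrence_histogram$n_otus), sum(detected))
  expect_setequal(v$sets$A, rownames(m)[pres[, "A"]])
})

test_that("the filter sweep is the identity at t = 0 and monotone in retained OTUs", {
  sim <- simulate_tables(simulation_config(n_otus = 300, depth = 8000, seed = 23))
  fs <- filter_sweep(sim$table, sim$design, thresholds = c(0, 1, 5, 10, 50))
  pt <- fs$per_threshold
  expect_equal(pt$otus_retained[1], sum(rowSums(as.matrix(sim$table)) > 0))
  base_dm <- bray_curtis(sim$table)
  base_within <- reproducibility(base_dm, sim$design)
  expect_equal(pt$within_mean[1],
               weighted.mean(base_within$mean_dissimilarity, base_within$n_pairs),
               tolerance = 1e-12)
  expect_true(all(diff(pt$otus_retained) <= 0))
  expect_true(all(pt$mean_overlap >= 0 & pt$mean_overlap <= 1, na.rm = TRUE))
  expect_equal(nrow(fs$regressions), 3L)
  expect_true(all(is.finite(fs$regressions$r_squared)))

  # a threshold removing everything is flagged and excluded
  fs2 <- filter_sweep(sim$table, sim$design, thresholds = c(1, 10^7))
  expect_true(fs2$per_threshold$empty[2])
})
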