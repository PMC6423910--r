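# hand-built distance matrix with perfect group separation: within-group
# distances all smaller than every between-group distance
separated_dm <- function(sizes, within = 0.1, between = 0.9, jitter = 0.01,
                         seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  g <- rep(seq_along(sizes), sizes)
  M <- matrix(0, n, n)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    base <- if (g[j] == g[k]) within else between
    M[k, j] <- M[j, k] <- base + runif(1, 0, jitter)
  }
  dimnames(M) <- list(paste0("s", 1:n), paste0("s", 1:n))
  as.dist(M)
}

test_that("ANOSIM gives R = 1 under complete separation and R near 0 under shuffled labels", {
  d <- design_for(c(3, 3))
  dm <- separated_dm(c(3, 3))
  res <- anosim(dm, d, n_permutations = 99, seed = 1)
  expect_equal(res$observed, 1)
  expect_true(res$p_value > 0 && res$p_value <= 1)

  # random relabelings of a fixed matrix: mean R over the null is ~0
  set.seed(5)
  dm15 <- separated_dm(c(5, 5, 5), jitter = 0.5)
  rs <- replicate(1000, anosim_R_oracle(dm15, sample(rep(LETTERS[1:3], each = 5))))
  expect_lt(abs(mean(rs)), 0.02)
  expect_true(all(rs >= -1 & rs <= 1))
})

test_that("ANOSIM matches vegan and the literal-definition oracle", {
  set.seed(12)
  ct <- random_table(30, 12)
  d <- design_for(c(4, 4, 4))
  dm <- bray_curtis(ct)
  mine <- anosim(dm, d, n_permutations = 99, seed = 3)
  expect_equal(mine$observed, anosim_R_oracle(dm, rep(c("A", "B", "C"), each = 4)),
               tolerance = 1e-12)
  veg <- vegan::anosim(dm, rep(c("A", "B", "C"), each = 4), permutations = 0)
  expect_equal(mine$observed, unname(veg$statistic), tolerance = 1e-12)
})

test_that("exhaustive enumeration on a perfectly separated 3+3 design gives p = 0.1", {
  d <- design_for(c(3, 3))
  dm <- separated_dm(c(3, 3))
  p_ex <- anosim_exhaustive_p(dm, rep(c("A", "B"), each = 3))
  expect_equal(p_ex, 2 / 20)
  res <- anosim(dm, d, n_permutations = 9999, seed = 2)
  se <- sqrt(p_ex * (1 - p_ex) / 9999)
  expect_lt(abs(res$p_value - p_ex), 3 * se + 2e-4)
})

test_that("PERMANOVA pseudo-F equals classical one-way ANOVA F on univariate data", {
  set.seed(9)
  y <- c(rnorm(4, 0), rnorm(4, 1), rnorm(4, 3))
  names(y) <- paste0("s", 1:12)
  d <- design_for(c(4, 4, 4))
  dm <- dist(y)
  attr(dm, "Labels") <- names(y)
  res <- permanova(dm, d, n_permutations = 99, seed = 1)
  f_classic <- summary(stats::aov(y ~ rep(c("A", "B", "C"), each = 4)))[[1]][["F value"]][1]
  expect_equal(res$F, f_classic, tolerance = 1e-9)
  expect_true(res$R2 >= 0 && res$R2 <= 1)

  # and cross-module: group_difference_test one-way ANOVA agrees too
  gd <- group_difference_test(y, d, "one_way_anova")
  expect_equal(gd$statistic, res$F, tolerance = 1e-9)
})

test_that("PERMANOVA agrees with vegan::adonis2 and flags the degenerate all-zero case", {
  set.seed(15)
  ct <- random_table(25, 10)
  d <- design_for(c(5, 5))
  dm <- bray_curtis(ct)
  res <- permanova(dm, d, n_permutations = 99, seed = 1)
  comm <- t(relative_abundance(ct))
  grp <- data.frame(g = rep(c("A", "B"), each = 5))
  veg <- vegan::adonis2(comm ~ g, data = grp, permutations = 2, method = "bray")
  expect_equal(res$F, veg$F[1], tolerance = 1e-9)
  expect_equal(res$R2, veg$R2[1], tolerance = 1e-9)

  zero <- as.dist(matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6))))
  dz <- permanova(zero, design_for(c(3, 3)))
  expect_true(dz$degenerate)
  expect_true(is.na(dz$p_value))
})

test_that("SIMPER identities hold and match the brute-force double loop", {
  set.seed(18)
  for (i in 1:10) {
    ct <- random_table(10, 6)
    d <- design_for(c(3, 3))
    res <- simper(ct, d)
    pair <- res$pairs[["A_vs_B"]]
    # contributions sum to the mean between-group Bray-Curtis
    dm <- bray_curtis(ct)
    M <- as.matrix(dm)
    between <- mean(M[1:3, 4:6])
    expect_equal(pair$overall_dissimilarity, between, tolerance = 1e-9)
    expect_equal(sum(pair$otu$percent), 100, tolerance = 1e-9)
    expect_equal(sum(pair$otu$average), pair$overall_dissimilarity,
                 tolerance = 1e-12)
    # brute-force recomputation
    oracle <- simper_oracle(ct, d, "A", "B")
    expect_equal(pair$otu$average,
                 unname(oracle[pair$otu$otu_id]), tolerance = 1e-12)
  }
})

test_that("SIMPER attributes dissimilarity to exactly the differing OTUs", {
  # rel abundances A = (0.5, 0.5, 0), B = (0.5, 0, 0.5): o1 contributes
  # nothing, o2 and o3 split the dissimilarity evenly
  m <- matrix(0L, 3, 6, dimnames = list(paste0("o", 1:3), paste0("s", 1:6)))
  m[1, ] <- 10L
  m[2, 1:3] <- 10L
  m[3, 4:6] <- 10L
  ct <- count_table(m)
  d <- design_for(c(3, 3))
  res <- simper(ct, d)
  otu <- res$pairs[["A_vs_B"]]$otu
  expect_equal(otu$percent[otu$otu_id == "o1"], 0, tolerance = 1e-9)
  expect_equal(otu$percent[otu$otu_id == "o2"], 50, tolerance = 1e-9)
  expect_equal(otu$percent[otu$otu_id == "o3"], 50, tolerance = 1e-9)
  expect_equal(res$pairs[["A_vs_B"]]$overall_dissimilarity, 0.5,
               tolerance = 1e-12)

  asg <- classify_otus(ct)
  res2 <- simper(ct, d, asg)
  cp <- res2$category_percent$aggregate
  expect_equal(sum(cp$percent), 100, tolerance = 1e-9)
})

test_that("multi-group SIMPER reports every pair plus the mean-over-pairs aggregate", {
  set.seed(25)
  ct <- random_table(15, 9)
  d <- design_for(c(3, 3, 3))
  res <- simper(ct, d)
  expect_length(res$pairs, 3L)
  per_pair <- vapply(res$pairs, function(x) x$overall_dissimilarity, numeric(1))
  expect_equal(res$aggregate$overall_dissimilarity, mean(per_pair),
               tolerance = 1e-12)
})

test_that("IndVal recovers perfect and uniform indicators with the >50 & p<0.05 validity rule", {
  # perfect indicator of group A (A = 1 and B = 1 no matter what else is
  # in the table, since it is absent from every other group)
  m <- matrix(0L, 2, 15, dimnames = list(c("perfect", "filler"),
                                         paste0("s", 1:15)))
  m["perfect", 1:3] <- 20L
  m["filler", ] <- 10L
  ct <- count_table(m)
  d <- design_for(c(3, 3, 3, 3, 3))
  res <- indicator_species(ct, d, n_permutations = 199, seed = 4)
  perfect <- res[res$otu_id == "perfect", ]
  expect_equal(perfect$indval, 100)
  expect_equal(perfect$A, 1)
  expect_equal(perfect$B, 1)
  expect_identical(perfect$best_group, "A")
  expect_true(all(res$valid == (res$indval > 50 & res$p_value < 0.05)))
  expect_true(all(res$indval >= 0 & res$indval <= 100))

  # an OTU spread evenly over 5 groups: A = 1/5, B = 1, IndVal = 20
  m1 <- matrix(10L, 1, 15, dimnames = list("uniform", paste0("s", 1:15)))
  res1 <- indicator_species(count_table(m1), d, n_permutations = 99, seed = 4)
  expect_equal(res1$indval, 100 / 5)
  expect_false(res1$valid)
})

test_that("classical group tests delegate correctly", {
  d2 <- design_for(c(3, 3))
  v <- setNames(c(1, 2, 3, 10, 11, 12), paste0("s", 1:6))
  mw <- group_difference_test(v, d2, "mann_whitney_u")
  expect_equal(unname(mw$statistic), 0)  # lower group wins no pairs

  same <- setNames(rep(c(5, 6, 7), 2), paste0("s", 1:6))
  kw <- group_difference_test(same, d2, "kruskal_wallis")
  expect_equal(kw$p_value, 1, tolerance = 1e-9)

  expect_error(group_difference_test(setNames(1:3, paste0("s", 1:3)),
                                     design_for(c(2, 1)), "one_way_anova"),
               ">= 2 observations")
})

test_that("permutation p-values follow the (hits+1)/(N+1) convention and reproduce under a seed", {
  set.seed(33)
  ct <- random_table(20, 10)
  d <- design_for(c(5, 5))
  dm <- bray_curtis(ct)
  a1 <- anosim(dm, d, n_permutations = 199, seed = 11)
  a2 <- anosim(dm, d, n_permutations = 199, seed = 11)
  expect_identical(a1$p_value, a2$p_value)
  expect_true(a1$p_value >= 1 / 200 && a1$p_value <= 1)
  expect_equal((a1$p_value * 200) %% 1, 0, tolerance = 1e-9)
})
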