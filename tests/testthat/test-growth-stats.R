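test_that("two-way ANOVA reproduces a hand-computed 2x2 decomposition", {
  # treatment effect only: cells (L1,G1)={1,2} (L1,G2)={1,2}
  #                        (L2,G1)={3,4} (L2,G2)={3,4}
  grid <- expand.grid(replicate = 1:2, treatment = c("L1", "L2"),
                      clone = c("G1", "G2"), stringsAsFactors = FALSE)
  grid$parameter <- "SL"
  grid$value <- ifelse(grid$treatment == "L1", 0, 2) + grid$replicate
  res <- two_way_anova(growth_trial(grid), "SL")
  tab <- res$table
  expect_equal(tab$sum_sq[tab$term == "treatment"], 8)
  expect_equal(tab$sum_sq[tab$term == "clone"], 0)
  expect_equal(tab$sum_sq[tab$term == "interaction"], 0)
  expect_equal(tab$sum_sq[tab$term == "residual"], 2)
  expect_equal(sum(tab$df), nrow(grid) - 1)
})

test_that("ANOVA agrees with stats::aov on random balanced designs", {
  set.seed(21)
  for (i in 1:5) {
    trial <- random_trial(a = 4, b = 2, n = 3)
    res <- two_way_anova(trial, "SL")
    ref <- summary(stats::aov(
      value ~ treatment * clone,
      data = transform(as.data.frame(trial),
                       treatment = factor(treatment), clone = factor(clone))
    ))[[1]]
    expect_equal(res$table$sum_sq, ref[["Sum Sq"]], tolerance = 1e-10)
    expect_equal(res$table$df, ref[["Df"]])
    expect_equal(res$table$p[1:3], ref[["Pr(>F)"]][1:3], tolerance = 1e-10)
  }
})

test_that("sums of squares are conserved", {
  set.seed(22)
  for (i in 1:10) {
    trial <- random_trial()
    res <- two_way_anova(trial, "SL")
    total <- sum((trial$value - mean(trial$value))^2)
    expect_equal(sum(res$table$sum_sq), total, tolerance = 1e-9)
  }
})

test_that("null data yields non-significant effects, injected effects star", {
  # identical cell means, within-cell noise only
  set.seed(23)
  grid <- expand.grid(replicate = 1:3, treatment = c("C", "T1", "T2", "T3"),
                      clone = c("TV22", "TV26"), stringsAsFactors = FALSE)
  grid$parameter <- "SL"
  grid$value <- 10 + rep(rnorm(3, sd = 0.5), 8)  # same noise in every cell
  res <- two_way_anova(growth_trial(grid), "SL")
  expect_lt(res$table$f[1], 1e-10)
  expect_equal(res$table$stars[1:3], c("ns", "ns", "ns"))

  # strong treatment effect (3 sigma) stars the treatment term in >= 95%
  # of seeded replications
  hits <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    set.seed(1000 + s)
    grid$value <- rnorm(nrow(grid), 10, 1) + ifelse(grid$treatment == "C", 0, 3)
    r <- two_way_anova(growth_trial(grid), "SL")
    if (r$table$p[1] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("ANOVA rejects malformed designs and flags thin ones", {
  grid <- expand.grid(replicate = 1:3, treatment = c("C", "T1"),
                      clone = c("A", "B"), stringsAsFactors = FALSE)
  grid$parameter <- "SL"; grid$value <- rnorm(nrow(grid), 10)
  expect_error(two_way_anova(growth_trial(grid[grid$clone == "A", ]), "SL"),
               "2 levels")
  expect_error(two_way_anova(growth_trial(grid[-(1:3), ]), "SL"),
               "empty design cell|unbalanced")
  expect_error(two_way_anova(growth_trial(grid[-1, ]), "SL"), "unbalanced")
  one_rep <- grid[grid$replicate == 1, ]
  one_rep$value <- rnorm(4, 10)
  expect_warning(two_way_anova(growth_trial(one_rep), "SL"), "interaction")
})

test_that("Welch treatment-vs-control contrasts are reported per clone", {
  set.seed(25)
  trial <- simulate_growth_trial(simulation_config(
    seed = 25, growth_baselines = c(SL = 30),
    growth_effects = c(C = 1, T1 = 1, T2 = 1, T3 = 2)))
  res <- two_way_anova(trial, "SL")
  expect_equal(nrow(res$pairwise), 6)  # 3 arms x 2 clones
  expect_true(all(res$pairwise$stars[res$pairwise$treatment == "T3"] != "ns"))
  expect_match(attr(res$pairwise, "assumption"), "Welch")
})

test_that("correlation PCA: structure, conservation and sign convention", {
  set.seed(26)
  trial <- simulate_growth_trial(simulation_config(seed = 26))
  pc <- pca_correlation(trial)
  expect_equal(sum(pc$explained_variance_pct), 100)
  # orthonormal loadings
  expect_equal(crossprod(pc$loadings),
               diag(ncol(pc$loadings)), ignore_attr = TRUE, tolerance = 1e-10)
  # deterministic: identical on re-run
  pc2 <- pca_correlation(trial)
  expect_identical(pc$loadings, pc2$loadings)
  expect_identical(pc$scores, pc2$scores)
  # largest-magnitude loading per component is positive
  for (j in seq_len(ncol(pc$loadings))) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
})

test_that("PCA explains 100% on rank-1 structure and splits uncorrelated data", {
  # two perfectly correlated parameters
  grid <- expand.grid(replicate = 1:5, treatment = c("C", "T1"),
                      clone = c("A", "B"), stringsAsFactors = FALSE)
  set.seed(27)
  base <- rnorm(nrow(grid), 10)
  d1 <- cbind(grid, parameter = "P1", value = base)
  d2 <- cbind(grid, parameter = "P2", value = 2 * base + 5)
  pc <- pca_correlation(growth_trial(rbind(d1, d2)))
  expect_equal(pc$explained_variance_pct[1], 100, tolerance = 1e-8)

  # standardized uncorrelated parameters: variance splits evenly (large n)
  set.seed(28)
  n_obs <- 10000
  grid <- data.frame(replicate = seq_len(n_obs), treatment = "C", clone = "A")
  long <- do.call(rbind, lapply(1:4, function(k) {
    cbind(grid, parameter = paste0("P", k), value = abs(rnorm(n_obs, 100, 10)))
  }))
  pc <- pca_correlation(growth_trial(long))
  expect_equal(pc$explained_variance_pct,
               rep(25, 4), tolerance = 0.08)  # 2% of the total scale
})

test_that("PCA is invariant to affine rescaling of a parameter", {
  set.seed(29)
  trial <- simulate_growth_trial(simulation_config(seed = 29))
  rescaled <- as.data.frame(trial)
  sel <- rescaled$parameter == "SL"
  rescaled$value[sel] <- rescaled$value[sel] * 3 + 7
  pc1 <- pca_correlation(trial)
  pc2 <- pca_correlation(growth_trial(rescaled))
  expect_equal(pc1$explained_variance_pct, pc2$explained_variance_pct,
               tolerance = 1e-10)
  expect_equal(pc1$loadings, pc2$loadings, tolerance = 1e-8)
})

test_that("PCA rejects zero-variance parameters by name", {
  grid <- expand.grid(replicate = 1:3, treatment = c("C", "T1"),
                      clone = c("A", "B"), stringsAsFactors = FALSE)
  flat <- cbind(grid, parameter = "FLAT", value = 5)
  set.seed(30)
  ok <- cbind(grid, parameter = "OK", value = rnorm(nrow(grid), 10))
  expect_error(pca_correlation(growth_trial(rbind(flat, ok))), "FLAT")
})

test_that("fold change matches hand arithmetic and is antisymmetric", {
  grid <- expand.grid(replicate = 1:3, treatment = c("C", "T1"),
                      clone = "A", stringsAsFactors = FALSE)
  grid$parameter <- "SL"
  grid$value <- ifelse(grid$treatment == "C", 1.5, 4.5)
  trial <- growth_trial(grid)
  fc <- fold_change(trial, "SL", "A", "T1")
  expect_equal(fc$ratio, 3)
  expect_equal(fc$log2_ratio, log2(3))

  # equal means: ratio 1, log2 0
  grid$value <- 2
  fc <- fold_change(growth_trial(grid), "SL", "A", "T1")
  expect_equal(fc$ratio, 1)
  expect_equal(fc$log2_ratio, 0)

  # doubling: ratio 2, log2 1
  grid$value <- ifelse(grid$treatment == "C", 2, 4)
  fc <- fold_change(growth_trial(grid), "SL", "A", "T1")
  expect_equal(c(fc$ratio, fc$log2_ratio), c(2, 1))

  # swapping treatment and control negates the log2 ratio
  rev <- fold_change(growth_trial(grid), "SL", "A", "C", control = "T1")
  expect_equal(rev$log2_ratio, -fc$log2_ratio)

  # zero control undefined
  grid$value <- ifelse(grid$treatment == "C", 0, 4)
  expect_warning(fc0 <- fold_change(growth_trial(grid), "SL", "A", "T1"),
                 "undefined")
  expect_true(is.na(fc0$ratio))
})

test_that("fold-change table covers every parameter/clone/arm cell", {
  trial <- simulate_growth_trial(simulation_config(seed = 31))
  fc <- fold_change_table(trial)
  expect_equal(nrow(fc), 9 * 2 * 3)
  expect_equal(fc$log2_ratio, log2(fc$ratio))
})
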