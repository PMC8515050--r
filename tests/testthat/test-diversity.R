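test_that("Shannon index matches closed forms and direct summation", {
  expect_equal(shannon(42), 0)
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  # direct summation oracle for the leaf compartment
  p <- leaf_counts / sum(leaf_counts)
  expect_equal(shannon(leaf_counts), -sum(p * log(p)))
  expect_equal(round_half_up(shannon(leaf_counts), 1), 2.3)
  expect_equal(round_half_up(shannon(root_counts), 2), 2.14)
  # base conversion
  expect_equal(shannon(leaf_counts, base = 2), shannon(leaf_counts) / log(2))
  expect_true(is.na(shannon(c(0, 0))))
})

test_that("Simpson dominance supports biased and bias-corrected forms", {
  # hand-counted: sum n(n-1) = 226 over N(N-1) = 43*42
  expect_equal(simpson_dominance(leaf_counts), 226 / 1806)
  expect_equal(round_half_up(simpson_dominance(leaf_counts), 3), 0.125)
  expect_equal(round_half_up(simpson_dominance(root_counts), 3), 0.177)
  expect_equal(simpson_dominance(9), 1)             # single taxon dominates
  expect_equal(simpson_dominance(c(1, 1)), 0)       # no repeated draws
  expect_equal(simpson_dominance(c(2, 1), "biased"), (2 / 3)^2 + (1 / 3)^2)
  expect_true(is.na(simpson_dominance(1)))          # N < 2 undefined
})

test_that("biased and unbiased Simpson converge for large N", {
  props <- c(0.5, 0.3, 0.15, 0.05)
  counts <- round(props * 1000)
  d <- abs(simpson_dominance(counts) - simpson_dominance(counts, "biased"))
  expect_lt(d, 1e-3)
})

test_that("dominance and richness indices match their formulas", {
  expect_equal(berger_parker(leaf_counts), 13 / 43)
  expect_equal(round_half_up(berger_parker(leaf_counts), 3), 0.302)
  expect_equal(round_half_up(berger_parker(root_counts), 3), 0.381)
  expect_equal(berger_parker(c(2, 2, 2)), 1 / 3)

  expect_equal(margalef(15, 43), 14 / log(43))
  expect_equal(round_half_up(margalef(15, 43), 2), 3.72)
  expect_equal(round_half_up(margalef(16, 63), 2), 3.62)
  expect_equal(margalef(1, 10), 0)
  expect_true(is.na(margalef(3, 1)))

  expect_equal(menhinick(15, 43), 15 / sqrt(43))
  expect_equal(round_half_up(menhinick(15, 43), 2), 2.29)
  expect_equal(round_half_up(menhinick(16, 63), 2), 2.02)
  expect_equal(menhinick(1, 1), 1)

  expect_equal(mean_abundance(15, 43), 43 / 15)
  expect_equal(round_half_up(mean_abundance(15, 43), 2), 2.87)
  expect_equal(round_half_up(mean_abundance(16, 63), 2), 3.94)
  expect_equal(mean_abundance(10, 10), 1)
  expect_true(is.na(mean_abundance(0, 0)))
})

test_that("evenness variants behave as documented", {
  expect_equal(evenness(c(5, 5, 5)), 1)
  expect_equal(evenness(c(5, 5, 5), "hill"), 1)
  expect_equal(evenness(leaf_counts), shannon(leaf_counts) / log(15))
  expect_equal(evenness(leaf_counts, "hill"), exp(shannon(leaf_counts)) / 15)
  # neither formula reproduces the historically reported 0.62: both are
  # exposed so the discrepancy is visible, not silently resolved
  expect_equal(evenness(leaf_counts), 0.8486, tolerance = 1e-3)
  expect_equal(evenness(leaf_counts, "hill"), 0.6636, tolerance = 1e-3)
  expect_true(is.na(evenness(7)))  # Pielou undefined at S = 1
})

test_that("indices agree with vegan on the fixture counts", {
  skip_if_not_installed("vegan")
  expect_equal(shannon(leaf_counts),
               unname(vegan::diversity(leaf_counts, "shannon")))
  expect_equal(simpson_dominance(leaf_counts, "biased"),
               unname(1 - vegan::diversity(leaf_counts, "simpson")))
  expect_equal(shannon(root_counts),
               unname(vegan::diversity(root_counts, "shannon")))
})

test_that("all indices are invariant to taxon permutation", {
  set.seed(9)
  for (i in 1:5) {
    perm <- sample(leaf_counts)
    expect_equal(shannon(perm), shannon(leaf_counts))
    expect_equal(simpson_dominance(perm), simpson_dominance(leaf_counts))
    expect_equal(berger_parker(perm), berger_parker(leaf_counts))
    expect_equal(evenness(perm), evenness(leaf_counts))
  }
})

test_that("merging taxa lowers Shannon, splitting raises it", {
  set.seed(10)
  for (i in 1:10) {
    counts <- rmultinom(1, 60, prob = runif(8))[, 1]
    counts <- counts[counts > 0]
    if (length(counts) < 2) next
    merged <- c(counts[1] + counts[2], counts[-(1:2)])
    expect_lte(shannon(merged), shannon(counts) + 1e-12)
    even_taxon <- counts[counts %% 2 == 0 & counts > 0][1]
    if (!is.na(even_taxon)) {
      idx <- which(counts == even_taxon)[1]
      split <- c(counts[-idx], even_taxon / 2, even_taxon / 2)
      expect_gt(shannon(split), shannon(counts))
    }
  }
})

test_that("diversity profile assembles every index for a compartment", {
  tab <- tea_genus_counts()
  leaf <- diversity_profile(tab, "leaf")
  expect_equal(leaf$richness_s, 15)
  expect_equal(leaf$total_n, 43)
  expect_equal(unname(leaf$display["simpson_d"]), 0.125)
  expect_equal(unname(leaf$display["berger_parker"]), 0.302)
  root <- diversity_profile(tab, "root")
  expect_equal(root$richness_s, 16)
  expect_equal(unname(root$display["margalef"]), 3.62)
  expect_error(diversity_profile(tab, "stem"), "compartment")
})

test_that("relative abundance sums to 100 and ranks the dominant taxon", {
  tab <- taxon_count_table(data.frame(taxon = c("A", "B"), x = c(13, 30)))
  ra <- relative_abundance(tab, "x")
  expect_equal(round_half_up(unname(ra), 2), c(30.23, 69.77))
  expect_equal(sum(ra), 100)

  leaf_ra <- relative_abundance(tea_genus_counts(), "leaf")
  expect_equal(names(which.max(leaf_ra)), "Alcaligenes")
  expect_equal(round_half_up(max(leaf_ra), 2), 30.23)
  expect_equal(sum(leaf_ra), 100)

  single <- taxon_count_table(data.frame(taxon = "A", x = 5))
  expect_equal(unname(relative_abundance(single, "x")), 100)
  zero <- taxon_count_table(data.frame(taxon = "A", x = 0))
  expect_error(relative_abundance(zero, "x"), "zero total")
})
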