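# shared fixtures built in code

# genus counts of the two compartments (leaf N = 43, S = 15; root N = 63,
# S = 16) used throughout the diversity tests
leaf_counts <- c(3, 3, 3, 1, 3, 2, 13, 1, 2, 7, 1, 1, 1, 1, 1)
root_counts <- c(7, 1, 8, 1, 5, 3, 1, 24, 1, 1, 1, 2, 1, 2, 1, 4)

# minimal trait-table builder: all binary columns default negative, all
# quantitative columns 0; override per-column with named arguments. A binary
# positive for a quantified trait gets a token quantitative value so the
# "value > 0 iff positive" consistency rule holds.
make_trait_df <- function(n, ...) {
  df <- data.frame(
    isolate_id = sprintf("I%02d", seq_len(n)),
    genus = rep("Bacillus", n), tissue = rep("leaf", n),
    clone = rep("TV22", n), iaa = rep(0, n), phosphate = rep(0, n),
    ammonia = rep(0, n), siderophore = rep(0, n)
  )
  for (tr in trait_catalog()) df[[paste0(tr, "_positive")]] <- rep(FALSE, n)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  for (q in c("iaa", "phosphate", "ammonia", "siderophore")) {
    if (!q %in% names(over)) {
      df[[q]][df[[paste0(q, "_positive")]] %in% TRUE] <- 1
    }
  }
  df
}

make_trait_table <- function(n, ...) trait_table(make_trait_df(n, ...))

# balanced random growth trial for ANOVA property tests: a treatment levels
# x b clone levels x n replicates, one parameter, iid noise
random_trial <- function(a = 4, b = 2, n = 3, parameter = "SL") {
  grid <- expand.grid(replicate = seq_len(n),
                      treatment = paste0("L", seq_len(a)),
                      clone = paste0("G", seq_len(b)),
                      stringsAsFactors = FALSE)
  grid$parameter <- parameter
  grid$value <- abs(rnorm(nrow(grid), mean = 10, sd = 2))
  growth_trial(grid[c("clone", "treatment", "replicate", "parameter", "value")])
}

# independent projection-based ANOVA oracle: sums of squares as squared
# norms of differences between nested least-squares fits (sequential
# projections; identical to the classical decomposition when balanced)
projection_anova <- function(d) {
  y <- d$value
  A <- factor(d$treatment); B <- factor(d$clone)
  fit <- function(form) qr.fitted(qr(model.matrix(form)), y)
  f0 <- fit(y ~ 1)
  fA <- fit(y ~ A)
  fAB <- fit(y ~ A + B)
  fABi <- fit(y ~ A * B)
  c(treatment = sum((fA - f0)^2),
    clone = sum((fAB - fA)^2),
    interaction = sum((fABi - fAB)^2),
    residual = sum((y - fABi)^2))
}
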