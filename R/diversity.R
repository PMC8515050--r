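#' Shannon diversity index
#'
#' `H = -sum_i p_i log(p_i)` over taxa with positive counts, with
#' `p_i = n_i / N`. Natural log by default (nats); pass `base = 2` or
#' `base = 10` for other conventions.
#'
#' @param counts non-negative integer vector of per-taxon abundances.
#' @param base logarithm base; default `exp(1)`.
#' @return H, or `NA` (undefined) when all counts are zero.
#' @export
#' @examples
#' shannon(c(1, 1, 1, 1))  # log(4)
shannon <- function(counts, base = exp(1)) {
  counts <- check_counts(counts)
  n_total <- sum(counts)
  if (n_total == 0) return(NA_real_)
  p <- counts[counts > 0] / n_total
  -sum(p * log(p, base = base))
}

#' Simpson dominance index
#'
#' Probability that two individuals drawn from the assemblage belong to the
#' same taxon. The default is the bias-corrected (sampling-without-
#' replacement) form `sum n_i (n_i - 1) / (N (N - 1))`; `estimator =
#' "biased"` gives the naive plug-in `sum (n_i / N)^2`.
#'
#' @param counts non-negative integer vector of per-taxon abundances.
#' @param estimator `"unbiased"` (default) or `"biased"`.
#' @return dominance D in `[0, 1]`, or `NA` when undefined (`N < 2` for the
#'   unbiased form, `N = 0` for the biased form).
#' @export
#' @examples
#' simpson_dominance(c(2, 1))              # 2*1 / (3*2)
#' simpson_dominance(c(2, 1), "biased")    # (2/3)^2 + (1/3)^2
simpson_dominance <- function(counts, estimator = c("unbiased", "biased")) {
  estimator <- match.arg(estimator)
  counts <- check_counts(counts)
  n_total <- sum(counts)
  if (estimator == "unbiased") {
    if (n_total < 2) return(NA_real_)
    sum(counts * (counts - 1)) / (n_total * (n_total - 1))
  } else {
    if (n_total == 0) return(NA_real_)
    sum((counts / n_total)^2)
  }
}

#' Berger-Parker dominance index
#'
#' Proportional abundance of the single most abundant taxon, `n_max / N`.
#'
#' @param counts non-negative integer vector of per-taxon abundances.
#' @return index in `(0, 1]`, or `NA` when all counts are zero.
#' @export
berger_parker <- function(counts) {
  counts <- check_counts(counts)
  n_total <- sum(counts)
  if (n_total == 0) return(NA_real_)
  max(counts) / n_total
}

#' Margalef richness index
#'
#' `(S - 1) / log(N)` with `S` the number of observed taxa and `N` the total
#' number of individuals.
#'
#' @param s integer taxon richness.
#' @param n integer total count (must be >= 2 for a defined value).
#' @return index, or `NA` when `N <= 1`.
#' @export
margalef <- function(s, n) {
  if (n <= 1) return(NA_real_)
  (s - 1) / log(n)
}

#' Menhinick richness index
#'
#' `S / sqrt(N)`.
#'
#' @param s integer taxon richness.
#' @param n integer total count (>= 1).
#' @return index, or `NA` when `N = 0`.
#' @export
menhinick <- function(s, n) {
  if (n <= 0) return(NA_real_)
  s / sqrt(n)
}

#' Species evenness
#'
#' Pielou evenness `J = H / log(S)` (default) or Hill-ratio evenness
#' `E = exp(H) / S`, both computed from the natural-log Shannon index.
#' Uniform assemblages give 1 under either formula.
#'
#' @param counts non-negative integer vector of per-taxon abundances.
#' @param formula `"pielou"` (default) or `"hill"`.
#' @return evenness, or `NA` when undefined (`S < 2` for Pielou, `N = 0`
#'   for Hill).
#' @export
evenness <- function(counts, formula = c("pielou", "hill")) {
  formula <- match.arg(formula)
  counts <- check_counts(counts)
  s <- sum(counts > 0)
  h <- shannon(counts)
  if (is.na(h)) return(NA_real_)
  if (formula == "pielou") {
    if (s < 2) return(NA_real_)
    h / log(s)
  } else {
    exp(h) / s
  }
}

#' Mean abundance per taxon
#'
#' Average population size `N / S`: individuals per observed taxon.
#'
#' @param s integer taxon richness (> 0 for a defined value).
#' @param n integer total count.
#' @return ratio, or `NA` when `S = 0`.
#' @export
mean_abundance <- function(s, n) {
  if (s <= 0) return(NA_real_)
  n / s
}

check_counts <- function(counts) {
  if (length(counts) == 0L) abort_input("counts must be non-empty")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort_input("counts must be non-negative and finite")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    abort_input("counts must be integers")
  }
  round(counts)
}

#' Assemble and validate a taxon-by-compartment count table
#'
#' @param counts non-negative integer matrix (taxa in rows, compartments in
#'   columns) with row and column names, or a data.frame whose first column
#'   is the taxon label.
#' @return integer matrix of class `taxon_count_table`.
#' @export
taxon_count_table <- function(counts) {
  if (is.data.frame(counts)) {
    taxa <- counts[[1]]
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- taxa
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_input("count table needs taxon row names and compartment column names")
  }
  storage.mode(counts) <- "double"
  for (j in seq_len(ncol(counts))) check_counts(counts[, j])
  structure(counts, class = c("taxon_count_table", class(matrix())))
}

#' Full diversity profile of one compartment
#'
#' Computes every index reported for a compartment of a count table:
#' richness S, total N, Shannon H (nats), bias-corrected Simpson dominance,
#' evenness, Berger-Parker, Margalef, Menhinick and mean abundance. Indices
#' are returned unrounded; `display` carries each value rounded half-up to
#' its conventional reporting precision.
#'
#' @param counts per-taxon abundance vector for the compartment, or a
#'   `taxon_count_table` together with `compartment`.
#' @param compartment column name when `counts` is a table.
#' @param simpson `"unbiased"` (default) or `"biased"`.
#' @param evenness_formula `"pielou"` (default) or `"hill"`.
#' @return list of class `diversity_profile` with fields `compartment`,
#'   `richness_s`, `total_n`, `shannon_h`, `simpson_d`, `evenness`,
#'   `berger_parker`, `margalef`, `menhinick`, `mean_abundance`, and a
#'   `display` named vector rounded to 1-3 decimals.
#' @export
#' @examples
#' tab <- taxon_count_table(data.frame(taxon = c("A", "B"), leaf = c(3, 1)))
#' diversity_profile(tab, "leaf")
diversity_profile <- function(counts, compartment = NULL,
                              simpson = c("unbiased", "biased"),
                              evenness_formula = c("pielou", "hill")) {
  simpson <- match.arg(simpson)
  evenness_formula <- match.arg(evenness_formula)
  if (inherits(counts, "taxon_count_table")) {
    if (is.null(compartment) || !compartment %in% colnames(counts)) {
      abort_input("compartment must name a column of the count table")
    }
    counts <- counts[, compartment]
  }
  counts <- check_counts(counts)
  s <- sum(counts > 0)
  n <- sum(counts)
  prof <- list(
    compartment = compartment %||% "sample",
    richness_s = s,
    total_n = n,
    shannon_h = shannon(counts),
    simpson_d = simpson_dominance(counts, simpson),
    evenness = evenness(counts, evenness_formula),
    berger_parker = berger_parker(counts),
    margalef = margalef(s, n),
    menhinick = menhinick(s, n),
    mean_abundance = mean_abundance(s, n)
  )
  prof$display <- c(
    shannon_h = round_half_up(prof$shannon_h, 2),
    simpson_d = round_half_up(prof$simpson_d, 3),
    evenness = round_half_up(prof$evenness, 3),
    berger_parker = round_half_up(prof$berger_parker, 3),
    margalef = round_half_up(prof$margalef, 2),
    menhinick = round_half_up(prof$menhinick, 2),
    mean_abundance = round_half_up(prof$mean_abundance, 2)
  )
  structure(prof, class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat(sprintf("Diversity profile [%s]: S = %d, N = %d\n",
              x$compartment, x$richness_s, x$total_n))
  print(x$display)
  invisible(x)
}

#' Relative abundance of each taxon within a compartment
#'
#' `100 * n_i / N` per taxon; the values sum to 100 within floating
#' tolerance.
#'
#' @param x a `taxon_count_table`.
#' @param compartment column name.
#' @return named numeric vector of percentages, in table taxon order.
#' @export
relative_abundance <- function(x, compartment) {
  if (!compartment %in% colnames(x)) {
    abort_input("unknown compartment '", compartment, "'")
  }
  counts <- x[, compartment]
  n_total <- sum(counts)
  if (n_total == 0) abort_input("compartment '", compartment, "' has zero total")
  100 * counts / n_total
}

`%||%` <- function(a, b) if (is.null(a)) b else a
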