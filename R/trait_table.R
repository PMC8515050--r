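#' The in vitro trait catalog
#'
#' The nine plant-growth-promotion traits screened per isolate, in scoring
#' order: the two tiered quantitative traits (IAA production, phosphate
#' solubilization) followed by the seven one-point binary traits.
#'
#' @return character vector of trait labels.
#' @export
trait_catalog <- function() {
  c("iaa", "phosphate", "ammonia", "siderophore", "nitrogen_fixation",
    "acc_deaminase", "cellulase", "protease", "amylase")
}

# traits that also carry a quantitative assay value (unit in parentheses):
# iaa ug/mL, phosphate mg/L, ammonia umol/mL, siderophore psu
quantitative_traits <- function() c("iaa", "phosphate", "ammonia", "siderophore")

#' Assemble and validate a per-isolate trait table
#'
#' The central container of a screening campaign: one row per isolate with
#' its identity (id, genus, tissue of origin, host clone), the quantitative
#' assay values for the four quantified traits, and a positive/negative call
#' for each of the nine catalog traits (columns `<trait>_positive`, logical).
#'
#' Validation enforces: unique isolate ids; tissue in `{leaf, root}`;
#' quantitative values non-negative; and the consistency rule that a
#' quantitative value > 0 implies a positive binary call. A quantitative
#' value of exactly 0 means no activity and is coerced to binary-negative.
#' Missing binary cells are treated as negative with a warning.
#'
#' @param df data.frame with columns `isolate_id`, `genus`, `tissue`,
#'   `clone`, the four quantitative columns `iaa`, `phosphate`, `ammonia`,
#'   `siderophore`, and logical columns `<trait>_positive` for every trait in
#'   [trait_catalog()].
#' @return the validated data.frame with class `trait_table` and attribute
#'   `trait_catalog`.
#' @export
trait_table <- function(df) {
  required <- c("isolate_id", "genus", "tissue", "clone",
                quantitative_traits(),
                paste0(trait_catalog(), "_positive"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    abort_input("trait table is missing columns: ",
                paste(missing_cols, collapse = ", "))
  }
  dup <- df$isolate_id[duplicated(df$isolate_id)]
  if (length(dup) > 0L) {
    abort_input("duplicated isolate_id: ", paste(unique(dup), collapse = ", "))
  }
  bad_tissue <- setdiff(unique(df$tissue), c("leaf", "root"))
  if (length(bad_tissue) > 0L) {
    abort_input("tissue must be 'leaf' or 'root'; found: ",
                paste(bad_tissue, collapse = ", "))
  }
  for (q in quantitative_traits()) {
    v <- df[[q]]
    if (!is.numeric(v) || any(v < 0, na.rm = TRUE)) {
      abort_input("quantitative trait '", q, "' must be numeric and >= 0")
    }
  }
  bin_cols <- paste0(trait_catalog(), "_positive")
  n_missing <- 0L
  for (b in bin_cols) {
    v <- as.logical(df[[b]])
    n_missing <- n_missing + sum(is.na(v))
    v[is.na(v)] <- FALSE
    df[[b]] <- v
  }
  if (n_missing > 0L) {
    warning(sprintf("%d missing binary trait cell(s) treated as negative",
                    n_missing), call. = FALSE)
  }
  # quantitative > 0 implies binary-positive; exactly 0 implies negative
  for (q in quantitative_traits()) {
    pos <- df[[paste0(q, "_positive")]]
    inconsistent <- df[[q]] > 0 & !pos
    if (any(inconsistent, na.rm = TRUE)) {
      abort_input("isolate(s) with ", q, " > 0 but binary-negative: ",
                  paste(df$isolate_id[which(inconsistent)], collapse = ", "))
    }
    df[[paste0(q, "_positive")]][df[[q]] == 0] <- FALSE
  }
  structure(df, class = c("trait_table", "data.frame"),
            trait_catalog = trait_catalog())
}

check_trait <- function(x, trait) {
  if (!trait %in% attr(x, "trait_catalog")) {
    abort_input("unknown trait '", trait, "'; catalog: ",
                paste(attr(x, "trait_catalog"), collapse = ", "))
  }
}

#' Prevalence of a trait across the screened isolates
#'
#' Count and percentage of isolates positive for a trait, with the count
#' split by tissue of origin. The percentage is `100 * count / nrow`,
#' reported both unrounded and rounded half-up to one decimal.
#'
#' @param x a [trait_table()].
#' @param trait a trait label from [trait_catalog()].
#' @return list with `count`, `total`, `percent` (unrounded),
#'   `percent_display` (1 dp, half-up) and `by_tissue` (named integer
#'   vector of positive counts per tissue).
#' @export
prevalence <- function(x, trait) {
  check_trait(x, trait)
  pos <- x[[paste0(trait, "_positive")]]
  count <- sum(pos)
  total <- nrow(x)
  pct <- if (total == 0) 0 else 100 * count / total
  by_tissue <- vapply(
    c(leaf = "leaf", root = "root"),
    function(t) sum(pos & x$tissue == t),
    integer(1)
  )
  list(count = count, total = total, percent = pct,
       percent_display = round_half_up(pct, 1), by_tissue = by_tissue)
}

#' Isolates positive for every trait in a set
#'
#' Exact intersection of the per-trait positive sets; with an empty trait
#' set every isolate qualifies (the intersection over nothing), which is the
#' documented convention.
#'
#' @param x a [trait_table()].
#' @param traits character vector of trait labels.
#' @return character vector of isolate ids, in table order.
#' @export
isolates_with_all <- function(x, traits) {
  for (tr in traits) check_trait(x, tr)
  keep <- rep(TRUE, nrow(x))
  for (tr in traits) keep <- keep & x[[paste0(tr, "_positive")]]
  x$isolate_id[keep]
}

#' Isolate counts and percentages by tissue of origin
#'
#' @param x a [trait_table()].
#' @return data.frame with `tissue`, `count` and `percent` (2 dp, half-up)
#'   per observed tissue; zero rows (with a warning) for an empty table.
#' @export
tissue_counts <- function(x) {
  if (nrow(x) == 0L) {
    warning("empty trait table", call. = FALSE)
    return(data.frame(tissue = character(0), count = integer(0),
                      percent = numeric(0)))
  }
  tab <- table(factor(x$tissue))
  data.frame(
    tissue = names(tab),
    count = as.integer(tab),
    percent = round_half_up(100 * as.integer(tab) / nrow(x), 2),
    row.names = NULL
  )
}

#' Per-genus tally of isolates positive for a trait
#'
#' Counts positives per genus, ordered by descending count with alphabetical
#' tie-break; genera with no positives are dropped.
#'
#' @param x a [trait_table()].
#' @param trait a trait label from [trait_catalog()].
#' @return named integer vector (names are genera), descending.
#' @export
genus_tally <- function(x, trait) {
  check_trait(x, trait)
  pos <- x[[paste0(trait, "_positive")]]
  if (!any(pos)) return(stats::setNames(integer(0), character(0)))
  tab <- table(x$genus[pos])
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}
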