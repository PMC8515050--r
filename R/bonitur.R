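#' Configuration of the 13-point bonitur assessment scale
#'
#' The additive multi-trait scale used to rank isolates for in vivo testing:
#' IAA production and phosphate solubilization earn 0-3 tiered points each,
#' and seven binary traits (ammonia, siderophore, nitrogen fixation, ACC
#' deaminase, cellulase, protease, amylase) earn 1 point each, for a maximum
#' of 13.
#'
#' Tier boundaries default to 50/100 ug/mL for IAA and 30/60 mg/L for
#' phosphate. The published tier labels overlap at the boundaries
#' ("<= 50" and "50-100" both claim 50); the default closed-lower semantics
#' assign a boundary value to the lower tier (`1` on `(0, t1]`, `2` on
#' `(t1, t2)`, `3` on `[t2, Inf)`); set `boundary = "upper"` for the
#' alternative reading (`1` on `(0, t1)`, `2` on `[t1, t2]`, `3` on
#' `(t2, Inf)`).
#'
#' @param iaa_tiers two increasing IAA thresholds in ug/mL.
#' @param phosphate_tiers two increasing phosphate thresholds in mg/L.
#' @param unit_traits the seven 1-point traits.
#' @param boundary `"lower"` (default) or `"upper"` tier assignment for
#'   values landing exactly on a threshold.
#' @return list of class `bonitur_config` with a `max_score` field
#'   (`3 + 3 + length(unit_traits)`).
#' @export
bonitur_config <- function(iaa_tiers = c(50, 100),
                           phosphate_tiers = c(30, 60),
                           unit_traits = c("ammonia", "siderophore",
                                           "nitrogen_fixation",
                                           "acc_deaminase", "cellulase",
                                           "protease", "amylase"),
                           boundary = c("lower", "upper")) {
  boundary <- match.arg(boundary)
  for (tiers in list(iaa_tiers, phosphate_tiers)) {
    if (length(tiers) != 2L || !all(is.finite(tiers)) || tiers[1] >= tiers[2]) {
      abort_input("tier thresholds must be two strictly increasing numbers")
    }
  }
  structure(
    list(iaa_tiers = iaa_tiers, phosphate_tiers = phosphate_tiers,
         unit_traits = unit_traits, boundary = boundary,
         max_score = 6L + length(unit_traits)),
    class = "bonitur_config"
  )
}

#' Tiered 0-3 points for a quantitative trait value
#'
#' Maps a concentration to assessment points: 0 for no activity (value 0),
#' then 1/2/3 by the two tier thresholds. With the default closed-lower
#' boundary rule a value exactly at a threshold takes the lower tier; values
#' landing exactly on a threshold are flagged via the `on_boundary`
#' attribute since the published tier labels are ambiguous there.
#'
#' @param value non-negative concentration (vectorized).
#' @param tiers two increasing thresholds `(t1, t2)`.
#' @param boundary `"lower"` or `"upper"`; see [bonitur_config()].
#' @return integer points 0-3, with attribute `on_boundary` (logical).
#' @export
#' @examples
#' score_tiered(123.55, c(50, 100))  # 3
#' score_tiered(50, c(50, 100))      # 1 (boundary value, lower tier)
score_tiered <- function(value, tiers, boundary = "lower") {
  if (any(!is.finite(value)) || any(value < 0)) {
    abort_input("value must be non-negative")
  }
  if (tiers[1] >= tiers[2]) abort_input("tiers must be strictly increasing")
  pts <- if (boundary == "lower") {
    ifelse(value == 0, 0L,
      ifelse(value <= tiers[1], 1L,
        ifelse(value < tiers[2], 2L, 3L)))
  } else {
    ifelse(value == 0, 0L,
      ifelse(value < tiers[1], 1L,
        ifelse(value <= tiers[2], 2L, 3L)))
  }
  pts <- as.integer(pts)
  attr(pts, "on_boundary") <- value %in% tiers
  pts
}

#' Bonitur score cards for every isolate in a trait table
#'
#' Applies the tier rule to the quantitative IAA and phosphate values and
#' adds one point per positive unit trait, giving each isolate's component
#' points and total on the 13-point scale.
#'
#' @param x a [trait_table()].
#' @param config a [bonitur_config()].
#' @return data.frame of class `score_table`: `isolate_id`, `iaa_points`,
#'   `phosphate_points`, one `<trait>_points` column per unit trait,
#'   `total`.
#' @export
bonitur_score <- function(x, config = bonitur_config()) {
  if (!inherits(config, "bonitur_config")) {
    abort_input("config must be a bonitur_config")
  }
  missing_traits <- setdiff(config$unit_traits, attr(x, "trait_catalog"))
  if (length(missing_traits) > 0L) {
    warning("traits absent from table scored as 0: ",
            paste(missing_traits, collapse = ", "), call. = FALSE)
  }
  cards <- data.frame(
    isolate_id = x$isolate_id,
    iaa_points = as.integer(score_tiered(x$iaa, config$iaa_tiers,
                                         config$boundary)),
    phosphate_points = as.integer(score_tiered(x$phosphate,
                                               config$phosphate_tiers,
                                               config$boundary))
  )
  for (tr in config$unit_traits) {
    col <- paste0(tr, "_positive")
    pts <- if (col %in% names(x)) as.integer(x[[col]]) else 0L
    cards[[paste0(tr, "_points")]] <- pts
  }
  point_cols <- setdiff(names(cards), "isolate_id")
  cards$total <- as.integer(rowSums(cards[point_cols]))
  stopifnot(all(cards$total <= config$max_score))
  structure(cards, class = c("score_table", "data.frame"),
            max_score = config$max_score)
}

#' Rank isolates by bonitur total
#'
#' Orders score cards by descending total; ties are broken by higher IAA
#' points, then higher phosphate points, then lexicographic isolate id, and
#' the rule that decided each isolate's position is recorded in the
#' `tie_break` column. Ranks are ordinal (1, 2, ... n), not dense.
#'
#' @param cards a `score_table` from [bonitur_score()].
#' @return the score table sorted, with added `rank` and `tie_break`
#'   columns.
#' @export
rank_isolates <- function(cards) {
  if (nrow(cards) == 0L) abort_input("no score cards to rank")
  ord <- order(-cards$total, -cards$iaa_points, -cards$phosphate_points,
               cards$isolate_id)
  ranked <- cards[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  ranked$rank <- seq_len(nrow(ranked))
  # record which criterion separated each isolate from its predecessor
  tb <- character(nrow(ranked))
  tb[1] <- "total"
  if (nrow(ranked) > 1L) {
    for (i in 2:nrow(ranked)) {
      prev <- ranked[i - 1L, ]; cur <- ranked[i, ]
      tb[i] <- if (cur$total < prev$total) "total"
      else if (cur$iaa_points < prev$iaa_points) "iaa_points"
      else if (cur$phosphate_points < prev$phosphate_points) "phosphate_points"
      else "isolate_id"
    }
  }
  ranked$tie_break <- tb
  ranked
}
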