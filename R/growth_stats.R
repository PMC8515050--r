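#' Validate a long-format growth trial table
#'
#' Nursery-trial measurements in long format: one row per plant per
#' parameter with factors `clone` (host cultivar), `treatment` (control `C`
#' and inoculation arms `T1`/`T2`/`T3`), `replicate`, the measured
#' `parameter` (shoot/root length, leaf count, fresh/dry weights,
#' chlorophyll a/b) and its non-negative `value`. Balance (equal replicate
#' count per clone x treatment cell) is checked per parameter and reported.
#'
#' @param df data.frame with columns `clone`, `treatment`, `replicate`,
#'   `parameter`, `value`.
#' @return the data.frame with class `growth_trial` and attribute
#'   `balanced` (logical).
#' @export
growth_trial <- function(df) {
  required <- c("clone", "treatment", "replicate", "parameter", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    abort_input("growth table is missing columns: ",
                paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(df$value) || any(!is.finite(df$value)) || any(df$value < 0)) {
    abort_input("value must be non-negative and finite")
  }
  balanced <- all(vapply(split(df, df$parameter), function(d) {
    tab <- table(d$clone, d$treatment)
    length(unique(as.vector(tab))) == 1L
  }, logical(1)))
  structure(df, class = c("growth_trial", "data.frame"), balanced = balanced)
}

star_of <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Balanced two-way ANOVA for one growth parameter
#'
#' Decomposes the variation of one measured parameter into treatment, clone,
#' treatment-by-clone interaction and residual components using the
#' classical balanced-design formulas on cell and marginal means (in a
#' balanced layout all standard sum-of-squares types coincide). F ratios
#' come from the mean squares against the residual, p values from the F
#' distribution, and significance stars mark p < 0.05 / 0.01 / 0.001.
#' Per-treatment-versus-control Welch contrasts within each clone are
#' reported alongside, flagged as an assumption since the trial design does
#' not prescribe a post-hoc procedure.
#'
#' @param trial a [growth_trial()].
#' @param parameter which parameter to analyse.
#' @return list of class `anova_result`: `parameter`, `table` (data.frame
#'   with term, df, sum_sq, mean_sq, f, p, stars), `pairwise` (Welch
#'   treatment-vs-control contrasts per clone) and `balanced`.
#' @export
two_way_anova <- function(trial, parameter) {
  d <- trial[trial$parameter == parameter, , drop = FALSE]
  if (nrow(d) == 0L) abort_input("no rows for parameter '", parameter, "'")
  d$treatment <- factor(d$treatment)
  d$clone <- factor(d$clone)
  if (nlevels(d$treatment) < 2L || nlevels(d$clone) < 2L) {
    abort_input("need at least 2 levels per factor")
  }
  cell_n <- table(d$clone, d$treatment)
  if (any(cell_n == 0)) {
    empty <- which(cell_n == 0, arr.ind = TRUE)
    abort_input("empty design cell(s): ",
                paste(rownames(cell_n)[empty[, 1]],
                      colnames(cell_n)[empty[, 2]],
                      sep = ":", collapse = ", "))
  }
  if (length(unique(as.vector(cell_n))) != 1L) {
    abort_input("unbalanced design for '", parameter,
                "': classical sums of squares require equal cell sizes")
  }
  n_rep <- unique(as.vector(cell_n))
  if (n_rep < 2L) {
    warning("1 replicate per cell: interaction confounded with residual",
            call. = FALSE)
  }
  a <- nlevels(d$treatment); b <- nlevels(d$clone)
  grand <- mean(d$value)
  m_trt <- tapply(d$value, d$treatment, mean)
  m_cln <- tapply(d$value, d$clone, mean)
  m_cell <- tapply(d$value, list(d$clone, d$treatment), mean)

  ss_trt <- b * n_rep * sum((m_trt - grand)^2)
  ss_cln <- a * n_rep * sum((m_cln - grand)^2)
  ss_int <- n_rep * sum((m_cell -
                           outer(m_cln, m_trt, `+`) + grand)^2)
  fitted_cell <- m_cell[cbind(as.character(d$clone), as.character(d$treatment))]
  ss_res <- sum((d$value - fitted_cell)^2)
  df_trt <- a - 1L; df_cln <- b - 1L
  df_int <- df_trt * df_cln
  df_res <- nrow(d) - a * b

  ms <- c(ss_trt / df_trt, ss_cln / df_cln, ss_int / df_int,
          if (df_res > 0) ss_res / df_res else NA_real_)
  f <- ms[1:3] / ms[4]
  p <- stats::pf(f, c(df_trt, df_cln, df_int), df_res, lower.tail = FALSE)
  tab <- data.frame(
    term = c("treatment", "clone", "interaction", "residual"),
    df = c(df_trt, df_cln, df_int, df_res),
    sum_sq = c(ss_trt, ss_cln, ss_int, ss_res),
    mean_sq = ms,
    f = c(f, NA_real_),
    p = c(p, NA_real_),
    stars = c(star_of(p), "")
  )

  pairwise <- NULL
  if ("C" %in% levels(d$treatment)) {
    rows <- list()
    for (cl in levels(d$clone)) {
      ctrl <- d$value[d$clone == cl & d$treatment == "C"]
      for (tr in setdiff(levels(d$treatment), "C")) {
        trt <- d$value[d$clone == cl & d$treatment == tr]
        pv <- if (length(ctrl) > 1L && length(trt) > 1L &&
                  (stats::sd(ctrl) > 0 || stats::sd(trt) > 0)) {
          stats::t.test(trt, ctrl)$p.value  # Welch by default
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          clone = cl, treatment = tr, p = pv,
          stars = ifelse(is.na(pv), "ns", star_of(pv))
        )
      }
    }
    pairwise <- do.call(rbind, rows)
    attr(pairwise, "assumption") <-
      "Welch two-sample contrasts vs control; post-hoc procedure assumed"
  }

  structure(list(parameter = parameter, table = tab, pairwise = pairwise,
                 n_per_cell = n_rep, balanced = TRUE),
            class = "anova_result")
}

#' Correlation-matrix PCA of the growth parameters
#'
#' Pivots the trial to a wide observation-by-parameter matrix (one row per
#' clone x treatment x replicate plant), standardizes each parameter to zero
#' mean and unit variance, and extracts principal components of the
#' resulting correlation structure. Loading signs follow a deterministic
#' convention: within each component the largest-magnitude loading is made
#' positive, so repeated runs are bit-identical.
#'
#' @param trial a [growth_trial()].
#' @return list of class `pca_result`: `scores` (observations x components,
#'   with clone/treatment/replicate identifiers), `loadings` (parameters x
#'   components, orthonormal columns), `explained_variance_pct` (sums to
#'   100).
#' @export
pca_correlation <- function(trial) {
  wide <- stats::reshape(
    as.data.frame(trial)[c("clone", "treatment", "replicate", "parameter", "value")],
    idvar = c("clone", "treatment", "replicate"),
    timevar = "parameter", direction = "wide"
  )
  names(wide) <- sub("^value\\.", "", names(wide))
  params <- setdiff(names(wide), c("clone", "treatment", "replicate"))
  if (length(params) < 2L) abort_input("PCA needs at least 2 parameters")
  mat <- as.matrix(wide[params])
  if (anyNA(mat)) abort_input("incomplete observations: missing parameter values")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    abort_input("zero-variance parameter(s): ",
                paste(params[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  # deterministic sign convention: largest |loading| per component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- cbind(wide[c("clone", "treatment", "replicate")],
                  as.data.frame(pc$x))
  structure(list(scores = scores, loadings = pc$rotation,
                 explained_variance_pct = var_pct),
            class = "pca_result")
}

#' Treatment-versus-control fold change for one parameter
#'
#' Ratio of the treatment-arm mean to the control mean within a clone, with
#' its log2 (so up- and down-regulation are equidistant from 0).
#'
#' @param trial a [growth_trial()].
#' @param parameter measured parameter.
#' @param clone clone label.
#' @param treatment treatment arm (compared against `control`).
#' @param control control label, default `"C"`.
#' @return list of class `fold_change_result` with `parameter`, `clone`,
#'   `treatment`, `mean_treatment`, `mean_control`, `ratio`, `log2_ratio`;
#'   ratio and log2 are `NA` (undefined) when the control mean is zero.
#' @export
fold_change <- function(trial, parameter, clone, treatment, control = "C") {
  sel <- trial$parameter == parameter & trial$clone == clone
  trt <- trial$value[sel & trial$treatment == treatment]
  ctl <- trial$value[sel & trial$treatment == control]
  if (length(trt) == 0L || length(ctl) == 0L) {
    abort_input("no data for ", parameter, "/", clone, "/", treatment,
                " vs ", control)
  }
  m_t <- mean(trt); m_c <- mean(ctl)
  if (m_c == 0) {
    ratio <- NA_real_; l2 <- NA_real_
    warning("control mean is zero: fold change undefined", call. = FALSE)
  } else {
    ratio <- m_t / m_c
    l2 <- if (ratio > 0) log2(ratio) else NA_real_
  }
  structure(list(parameter = parameter, clone = clone, treatment = treatment,
                 mean_treatment = m_t, mean_control = m_c,
                 ratio = ratio, log2_ratio = l2),
            class = "fold_change_result")
}

#' Fold-change table over all parameters, clones and treatment arms
#'
#' @param trial a [growth_trial()].
#' @param control control label, default `"C"`.
#' @return data.frame with one row per parameter x clone x treatment arm.
#' @export
fold_change_table <- function(trial, control = "C") {
  params <- unique(trial$parameter)
  clones <- unique(trial$clone)
  arms <- setdiff(unique(trial$treatment), control)
  rows <- list()
  for (p in params) for (cl in clones) for (tr in arms) {
    fc <- fold_change(trial, p, cl, tr, control)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = p, clone = cl, treatment = tr,
      mean_treatment = fc$mean_treatment, mean_control = fc$mean_control,
      ratio = fc$ratio, log2_ratio = fc$log2_ratio
    )
  }
  do.call(rbind, rows)
}
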