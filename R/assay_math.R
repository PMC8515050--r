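#' Fit a linear standard curve to a calibration series
#'
#' Ordinary least-squares fit of `signal = intercept + slope * concentration`
#' to a standard series, as used to back-calculate IAA (Salkowski, 530 nm),
#' solubilized phosphate (molybdate, 650 nm) and ammonia (Nessler, 450 nm)
#' from absorbance readings. The regression is unweighted; blank subtraction,
#' if wanted, is the caller's responsibility.
#'
#' @param concentration numeric vector of standard concentrations.
#' @param signal numeric vector of measured signals (same length).
#' @param analyte label for the analyte (carried into provenance).
#' @param concentration_unit unit label, e.g. `"ug/mL"`, `"mg/L"`,
#'   `"umol/mL"`.
#' @return An object of class `standard_curve`: a list with `analyte`,
#'   `slope`, `intercept`, `r_squared`, `concentration_unit`, `n_points` and
#'   `invertible` (FALSE when the fitted slope is zero, i.e. a flat signal).
#' @export
#' @examples
#' fit_standard_curve(c(0, 1, 2), c(1, 3, 5))
fit_standard_curve <- function(concentration, signal, analyte = "analyte",
                               concentration_unit = "unit") {
  if (length(concentration) != length(signal)) {
    abort_input("concentration and signal must have the same length")
  }
  if (length(concentration) < 3L) {
    abort_input("a standard curve needs at least 3 calibration points")
  }
  if (length(unique(concentration)) < 2L) {
    abort_input("degenerate design: all standard concentrations are equal")
  }
  fit <- stats::lm(signal ~ concentration)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  ss_tot <- sum((signal - mean(signal))^2)
  r_squared <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(
      analyte = analyte,
      slope = slope,
      intercept = intercept,
      r_squared = r_squared,
      concentration_unit = concentration_unit,
      n_points = length(signal),
      invertible = slope != 0
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve [%s]: signal = %.4g + %.4g * conc (%s), r^2 = %.4f, n = %d%s\n",
    x$analyte, x$intercept, x$slope, x$concentration_unit, x$r_squared,
    x$n_points, if (!x$invertible) " [NON-INVERTIBLE]" else ""
  ))
  invisible(x)
}

#' Back-calculate concentration from a signal via a standard curve
#'
#' Inverts a fitted [fit_standard_curve()] line:
#' `(signal - intercept) / slope`. Negative back-calculated concentrations
#' (assay noise near the blank) are clamped to zero with a warning.
#'
#' @param curve a `standard_curve` object.
#' @param signal numeric vector of measured signals.
#' @return numeric vector of concentrations in `curve$concentration_unit`,
#'   with attribute `clamped` (logical vector) marking values clamped to 0.
#' @export
signal_to_concentration <- function(curve, signal) {
  if (!inherits(curve, "standard_curve")) {
    abort_input("curve must be a standard_curve object")
  }
  if (!curve$invertible) {
    abort_input("standard curve is non-invertible (slope is zero)")
  }
  conc <- (signal - curve$intercept) / curve$slope
  # values within floating error of zero are zeroed silently; genuinely
  # negative back-calculations (signal below the blank) warn
  clamped <- conc < -1e-9
  conc[conc < 0] <- 0
  if (any(clamped)) {
    warning(sprintf("%d concentration(s) below zero clamped to 0", sum(clamped)),
            call. = FALSE)
  }
  attr(conc, "clamped") <- clamped
  conc
}

#' Percent siderophore units from the CAS shuttle assay
#'
#' `psu = 100 * (Ar - As) / Ar`, where `Ar` is the absorbance of the
#' un-inoculated reference and `As` the absorbance of the sample, both at
#' 630 nm. Iron removal from the Chrome Azurol S dye complex lowers the
#' sample absorbance, so stronger chelation gives higher psu (at most 100).
#'
#' @param a_reference reference absorbance at 630 nm (must be > 0).
#' @param a_sample sample absorbance at 630 nm (>= 0).
#' @return percent siderophore units (numeric, vectorized).
#' @export
#' @examples
#' siderophore_psu(0.5, 0.4)  # 20
siderophore_psu <- function(a_reference, a_sample) {
  if (any(!is.finite(a_reference)) || any(a_reference <= 0)) {
    abort_input("a_reference must be positive")
  }
  if (any(!is.finite(a_sample)) || any(a_sample < 0)) {
    abort_input("a_sample must be non-negative")
  }
  100 * (a_reference - a_sample) / a_reference
}

#' Percent cell-surface hydrophobicity (MATH assay)
#'
#' `CSH = 100 * (A0 - A1) / A0`: the percent drop in aqueous-phase absorbance
#' at 400 nm after partitioning against a hydrocarbon, where `A0` is the
#' initial absorbance of the culture and `A1` the final aqueous-phase
#' absorbance.
#'
#' @param a_initial initial absorbance A0 at 400 nm (must be > 0).
#' @param a_final final aqueous-phase absorbance A1 at 400 nm.
#' @return percent hydrophobicity (numeric, vectorized).
#' @export
hydrophobicity_pct <- function(a_initial, a_final) {
  if (any(!is.finite(a_initial)) || any(a_initial <= 0)) {
    abort_input("a_initial must be positive")
  }
  100 * (a_initial - a_final) / a_initial
}

#' Chlorophyll a and b from DMSO-extract absorbances
#'
#' Arnon-style equations for a DMSO leaf extract read at 645 and 663 nm:
#' \deqn{Chl_a = (12.7 A_{663} - 2.69 A_{645}) \cdot V / (1000 W)}
#' \deqn{Chl_b = (22.9 A_{645} - 4.68 A_{663}) \cdot V / (1000 W)}
#' with `V` the extract volume in mL and `W` the fresh tissue mass in g
#' (the assay as run uses V = 7 mL and W = 0.1 g). Negative values, which
#' indicate a possible swap of the two wavelength readings, are flagged.
#'
#' @param a645 absorbance at 645 nm.
#' @param a663 absorbance at 663 nm.
#' @param volume_ml final extract volume V in mL (> 0); default 7.
#' @param mass_g fresh tissue mass W in g (> 0); default 0.1.
#' @return named list with `chl_a` and `chl_b` in mg per g fresh weight and
#'   `flagged_negative` (TRUE when either value is negative).
#' @export
#' @examples
#' chlorophyll_ab(0.25, 0.5)
chlorophyll_ab <- function(a645, a663, volume_ml = 7, mass_g = 0.1) {
  if (!all(is.finite(c(volume_ml, mass_g))) || volume_ml <= 0 || mass_g <= 0) {
    abort_input("volume_ml and mass_g must be positive")
  }
  scale <- volume_ml / (1000 * mass_g)
  chl_a <- (12.7 * a663 - 2.69 * a645) * scale
  chl_b <- (22.9 * a645 - 4.68 * a663) * scale
  flagged <- any(chl_a < 0 | chl_b < 0)
  if (flagged) {
    warning("negative chlorophyll value: check for swapped 645/663 nm readings",
            call. = FALSE)
  }
  list(chl_a = chl_a, chl_b = chl_b, flagged_negative = flagged)
}

#' Endophyte population density as log10 CFU per gram fresh tissue
#'
#' Converts a dilution-plate colony count to log10 colony-forming units per
#' gram: the plated aliquot of volume `plated_volume_ml` at dilution
#' `10^-dilution_exponent` contains `colonies` CFU, so the undiluted
#' suspension holds `colonies / (plated_volume_ml * 10^-k)` CFU per mL;
#' multiplied by the homogenate volume and divided by the tissue mass this
#' gives CFU per gram. The homogenate-volume convention defaults to 1 mL
#' (density per mL of suspension attributed per gram directly); declare the
#' actual suspension volume when it differs.
#'
#' @param colonies integer colony count (>= 0).
#' @param dilution_exponent k in the plated dilution 10^-k.
#' @param plated_volume_ml plated aliquot volume in mL.
#' @param sample_mass_g fresh tissue mass in g (> 0).
#' @param homogenate_volume_ml total suspension volume in mL (default 1).
#' @return log10 CFU per g, or `NA` with attribute
#'   `below_detection = TRUE` when no colonies were counted.
#' @export
#' @examples
#' log10_cfu_per_g(100, dilution_exponent = 2, plated_volume_ml = 0.1,
#'                 sample_mass_g = 1)  # 5
log10_cfu_per_g <- function(colonies, dilution_exponent, plated_volume_ml,
                            sample_mass_g, homogenate_volume_ml = 1) {
  stopifnot_scalar(colonies, "colonies")
  if (colonies < 0) abort_input("colonies must be non-negative")
  if (sample_mass_g <= 0) abort_input("sample_mass_g must be positive")
  if (plated_volume_ml <= 0) abort_input("plated_volume_ml must be positive")
  if (colonies == 0) {
    out <- NA_real_
    attr(out, "below_detection") <- TRUE
    return(out)
  }
  cfu_per_ml <- colonies / (plated_volume_ml * 10^(-dilution_exponent))
  log10(cfu_per_ml * homogenate_volume_ml / sample_mass_g)
}

#' Classify crystal-violet biofilm formation against a control cutoff
#'
#' Categorizes a 570 nm crystal-violet reading by the standard microtiter
#' convention: with cutoff `ODc` (the control OD, plus 3 SD when replicate
#' controls are supplied), a sample is `none` when `OD <= ODc`, `weak` when
#' `ODc < OD <= 2 ODc`, `moderate` when `2 ODc < OD <= 4 ODc` and `strong`
#' when `OD > 4 ODc`. The 2x/4x multipliers are exposed for laboratories
#' using a different convention.
#'
#' @param od570_sample sample OD at 570 nm (vectorized).
#' @param od570_control control OD at 570 nm: a single blank reading, or a
#'   vector of replicate controls (then `ODc = mean + 3 sd`).
#' @param multipliers cutoff multipliers for the weak/moderate and
#'   moderate/strong boundaries, default `c(2, 4)`.
#' @return factor with ordered levels `none < weak < moderate < strong`.
#' @export
#' @examples
#' classify_biofilm(c(0.05, 0.35, 0.50), 0.10)
classify_biofilm <- function(od570_sample, od570_control, multipliers = c(2, 4)) {
  if (any(!is.finite(od570_sample)) || any(od570_sample < 0) ||
      any(!is.finite(od570_control)) || any(od570_control < 0)) {
    abort_input("absorbances must be non-negative")
  }
  if (length(multipliers) != 2L || multipliers[1] <= 1 ||
      multipliers[2] <= multipliers[1]) {
    abort_input("multipliers must be increasing and > 1")
  }
  odc <- if (length(od570_control) > 1L) {
    mean(od570_control) + 3 * stats::sd(od570_control)
  } else {
    od570_control
  }
  lv <- c("none", "weak", "moderate", "strong")
  # boundaries are inclusive below: OD exactly at a cutoff stays in the lower class
  cat_of <- function(od) {
    if (od <= odc) "none"
    else if (od <= multipliers[1] * odc) "weak"
    else if (od <= multipliers[2] * odc) "moderate"
    else "strong"
  }
  factor(vapply(od570_sample, cat_of, character(1)), levels = lv, ordered = TRUE)
}

#' Summarize replicate assay measurements
#'
#' Mean, sample standard deviation (n - 1 denominator) and standard error of
#' a set of replicate readings; with a single replicate the dispersion is
#' reported as 0 and flagged.
#'
#' @param values numeric vector of replicate measurements (non-empty).
#' @return list with `mean`, `sd`, `se`, `n` and `single_replicate` flag.
#' @export
#' @examples
#' summarize_replicates(c(1, 2, 3))
summarize_replicates <- function(values) {
  if (length(values) == 0L) abort_input("values must be non-empty")
  if (any(!is.finite(values))) abort_input("values must be finite")
  n <- length(values)
  s <- if (n == 1L) 0 else stats::sd(values)
  list(
    mean = mean(values),
    sd = s,
    se = s / sqrt(n),
    n = n,
    single_replicate = n == 1L
  )
}
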