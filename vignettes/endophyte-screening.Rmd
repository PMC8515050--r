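---
title: "Methods: screening, scoring and diversity analysis of plant-growth-promoting endophytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, scoring and diversity analysis of plant-growth-promoting endophytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgpscreen)
```

## The problem

Culturable endophytic bacteria (EnB) isolated from crop tissues are screened
in vitro for plant-growth-promotion (PGP) traits — phytohormone (IAA)
production, phosphate solubilization, ammonia and siderophore production,
nitrogen fixation, ACC deaminase activity, and hydrolytic enzymes — and the
best performers are carried into nursery trials. `pgpscreen` implements the
computational side of such a campaign end to end: raw colorimetric signals
are converted to quantified traits, the per-isolate trait matrix is
summarized and intersected, isolates are ranked on an additive bonitur
scale, the genus composition of each tissue compartment is profiled with
alpha-diversity indices, and the nursery trial is analysed with balanced
two-way ANOVA, correlation-matrix PCA and treatment-versus-control fold
change. A seeded simulator generates synthetic campaigns with the same
statistical structure, so every pipeline stage is testable without any
external dataset.

## Assay conversions

Colorimetric assays are quantified against linear standard curves
(`fit_standard_curve()`, unweighted ordinary least squares;
`signal_to_concentration()` inverts the line). The regression is unweighted
because calibration series in these assays are short (typically 4–8 points)
and homoscedastic on the instrument's working range; blank subtraction is
left to the caller so the same machinery serves blanked and unblanked
series. Back-calculated concentrations within floating error of zero are
zeroed silently; genuinely negative values (signal below the blank, expected
from assay noise) are clamped to zero and flagged rather than propagated or
turned into errors.

Closed-form assay quantities:

* **Siderophore**, CAS shuttle assay: percent siderophore units
  $psu = 100\,(A_r - A_s)/A_r$ with both absorbances at 630 nm. Scale-free
  in the absorbances.
* **Cell-surface hydrophobicity**, MATH assay:
  $CSH = 100\,(A_0 - A_1)/A_0$ at 400 nm.
* **Chlorophyll**, DMSO extraction read at 645/663 nm:
  $Chl_a = (12.7A_{663} - 2.69A_{645})\,V/(1000\,W)$ and
  $Chl_b = (22.9A_{645} - 4.68A_{663})\,V/(1000\,W)$, in mg per g fresh
  weight, with defaults $V = 7$ mL extract and $W = 0.1$ g tissue (the assay
  volumes used here). The source formulas are typeset ambiguously in much of
  the applied literature; the bracketed reading above is the standard
  Arnon-style convention and is the one implemented. Negative outputs are
  flagged as a probable wavelength swap.
* **Plate counts**: `log10_cfu_per_g()` converts a dilution-plate count to
  log10 CFU per gram fresh tissue. The homogenate-volume convention defaults
  to 1 mL (the plated suspension's per-mL density attributed per gram
  directly); when the laboratory's protocol suspends tissue in a known
  volume — 10 mL per g is common — that volume is declared explicitly. Zero
  colonies return an explicit below-detection marker, never 0.
* **Biofilm**: crystal-violet OD at 570 nm classified against the control
  cutoff $OD_c$ by the widely used convention none $\le OD_c <$ weak
  $\le 2\,OD_c <$ moderate $\le 4\,OD_c <$ strong. The 2×/4× multipliers are
  arguments because the category names, not the thresholds, are what assay
  reports usually state. With replicate controls the cutoff is
  mean + 3 SD.

Replicate summaries (`summarize_replicates()`) report the mean, sample SD
(n − 1) and SE; published trait tables in this field print "mean ± x"
without saying whether x is SD or SE, so both are always carried.

## The trait table and the bonitur scale

`trait_table()` validates the per-isolate matrix: unique ids, tissue in
{leaf, root}, non-negative quantitative values, and the consistency rule
that a positive quantitative value implies a positive binary call while an
exact 0 means "no activity" and is coerced to negative. Missing binary
cells are treated as negative with a warning — screening tables in practice
leave untested cells blank, and silently dropping isolates would bias
prevalence. `prevalence()`, `tissue_counts()`, `genus_tally()` and
`isolates_with_all()` (the Venn-style intersection; an empty trait set
returns all isolates, the intersection over nothing) cover the descriptive
statistics. Display percentages round half away from zero (1 dp for
prevalences, 2 dp for tissue splits); unrounded values are always retained.

The **bonitur scale** awards 0–3 tiered points each for IAA
(thresholds 50/100 µg mL⁻¹) and phosphate solubilization (30/60 mg L⁻¹) and
1 point for each of seven binary traits, maximum 13. The published tier
labels ("1 ≤ 50, 2 = 50–100, 3 ≥ 100") overlap at the boundaries; the
implementation resolves this as 1 on (0, t₁], 2 on (t₁, t₂), 3 on [t₂, ∞) so
every value maps to exactly one tier, flags values landing exactly on a
threshold, and offers the alternative (left-open) reading via
`boundary = "upper"`. Ranking is by descending total with a deterministic
tie-break chain — higher IAA points, then higher phosphate points, then
lexicographic isolate id — recorded per row in a `tie_break` column. This
chain reproduces the component-ordered blocks seen in reference rankings;
within blocks that reference tables order arbitrarily, the id fallback makes
the output a reproducible total order. Ranks are ordinal (1…n), not dense.

## Diversity profile

From a genus × compartment count table, `diversity_profile()` computes
richness S, total N, Shannon $H = -\sum p_i \ln p_i$ (natural log; the log
base is an argument), Simpson dominance, Berger–Parker $n_{max}/N$, Margalef
$(S-1)/\ln N$, Menhinick $S/\sqrt N$, evenness, and mean abundance $N/S$.
Simpson defaults to the bias-corrected dominance form
$\sum n_i(n_i-1)/(N(N-1))$: on the bundled reference counts only this form
reproduces the published per-compartment values (0.125 leaf, 0.177 root),
so it is the default and the naive plug-in $\sum p_i^2$ is available by
flag. Evenness is offered as Pielou $H/\ln S$ (default) and Hill $e^H/S$;
on the bundled counts neither reproduces the historically reported values
(0.62 leaf / 0.516 root — the leaf value is even printed differently in
different places in the original report), so the package exposes both and
treats the reported evenness as unreproducible rather than picking a
formula post hoc. Undefined cases (N < 2, S < 2, all-zero columns) return
`NA` markers, never silent zeros.

```{r diversity}
counts <- tea_genus_counts()
diversity_profile(counts, "leaf")
diversity_profile(counts, "root")
```

## Growth-trial statistics

`two_way_anova()` decomposes one parameter of a balanced clone × treatment
trial from first principles (cell and marginal means): in a balanced layout
all classical sum-of-squares types coincide, which is why unbalanced inputs
are rejected with a message instead of silently switching SS type. F ratios
use the residual mean square; stars mark p < 0.05/0.01/0.001 on the
treatment main effect. Because trial reports in this field star individual
treatment-versus-control bars without naming a post-hoc procedure, Welch
two-sample contrasts within each clone are computed alongside and labelled
as an assumption in the output. No multiplicity correction is applied
across the nine growth parameters by default, matching common practice in
these reports; the p values are returned so any correction can be layered
on. With one replicate per cell the interaction is confounded with the
residual and the fit is flagged.

`pca_correlation()` standardizes each parameter (correlation-matrix PCA, so
parameters with different units contribute equally) and fixes loading signs
deterministically — the largest-magnitude loading of each component is made
positive — so repeated runs are bit-identical. `fold_change()` reports the
raw treatment/control ratio of means and its log2 side by side: applied
reports are often ambiguous about which scale a quoted "fold" is on, so
both are always emitted.

## The simulator

`simulation_config()` fixes the campaign structure the generators emulate:
106 isolates from 22 genera, split 43 leaf / 63 root, five host clones;
per-trait positive prevalences equal to the observed campaign fractions
(e.g. IAA 92/106, ammonia 101/106, amylase 20/106); quantitative positives
drawn from a lognormal truncated to the observed assay ranges (IAA
3.00–129.84 µg mL⁻¹, phosphate 2.79–81.42 mg L⁻¹, ammonia 0.61–4.92
µmol mL⁻¹, siderophore up to 83.22 psu) — right-skewed, matching the
observation that only a minority of producers are strong producers. Binary
traits default to independent Bernoulli draws; a `trait_association` knob
adds positive association so multi-trait isolates (the Venn-diagram centre)
appear at realistic rates. All-negative isolates are re-assigned their
single most prevalent trait, because a screening table by construction only
contains isolates that showed something. The growth generator uses
multiplicative lognormal noise (CV 10% by default; weights and lengths are
positive and right-skewed), per-treatment multipliers (defaults 1.3/1.3/1.5
for the two single-strain arms and the consortium, reflecting the stronger
consortium response such trials report) and a ±5% clone baseline contrast
so the clone effect is non-degenerate.

Each generator draws from its own seed stream derived from the master seed,
so adding a call to one generator never shifts the draws of another, and
the same seed always yields byte-identical tables.

What the simulator does *not* emulate: between-trait correlation structure
beyond the single association knob (unknowable from summary statistics),
genus–trait dependence (a *Bacillus* is no likelier to fix nitrogen than a
*Janibacter*), measurement error on the binary calls, and any spatial or
temporal structure in the nursery. Tests passing on simulated data
therefore demonstrate the correctness and calibration of the computations,
not the biological realism of any particular dataset.

## Numerical and design choices

* Display rounding is half away from zero (`round_half_up()`), matching how
  the reference percentages were evidently rounded; all persisted numbers
  are full precision.
* Problem sizes in the test suite: the ANOVA implementation is checked
  against an independent projection oracle on 200 random balanced 4 × 2 × 3
  designs (relative error < 1e-8), the treatment F test's type-I error is
  calibrated on 1,000 seeded null trials (accepted band 0.02–0.08 at
  α = 0.05), and fold-change recovery of an engineered 2× effect is checked
  over 100 seeds at 3 replicates. These sizes give the properties tight
  sampling envelopes while the whole suite stays fast.
* Ties in `genus_tally()` break alphabetically; ranking tie-breaks are
  recorded in the output so a reader can see which rule ordered each row.
* Readers are tolerant (unknown columns warn, never error) but strict on
  the schema itself (missing columns, duplicate ids and non-numeric cells
  error with the offenders named).

## Known limitations

* The bonitur tier ambiguity at exactly 50/100 (IAA) and 30/60 (phosphate)
  is resolvable only by convention; boundary hits are flagged.
* The reported evenness values cannot be reproduced from the bundled counts
  under either standard formula (see above) and are excluded from the
  reproduction checks.
* Fold-change "x-fold" language in applied reports may refer to either the
  raw ratio or its log2; downstream interpretation must pick one, which is
  why both are returned.
* The ANOVA is fixed-effects and balanced-only by design; mixed-effects or
  repeated-measures structures are out of scope.
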