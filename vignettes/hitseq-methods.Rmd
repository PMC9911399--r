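---
title: "Models and methods behind hitseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hitseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitseq)
```

## The assay and its signal

High Throughput Sequencing Equilibrium binding (HiTS-Eq) measures, in a
single experiment, the relative affinity of a protein for every member of
a randomized nucleic-acid pool. The pool — here all 4^7 = 16,384 RNA
7-mers embedded in a fixed construct — is equilibrated with the protein
at a series of concentrations, the *unbound* fraction is isolated and
sequenced, and each variant's depletion from the unbound pool relative to
a no-protein control is the raw signal of binding. Because protein (nM to
µM) is in vast excess over any individual RNA species (a 1 nM pool spread
over 16,384 variants), binding is pseudo-first-order: the free fraction
of a variant with dissociation constant $K$ at protein concentration $E$
is $K/(K+E)$, and ligand depletion of the protein is negligible.

## From depletion to relative affinities

For two species with constants $K_1$ (a reference, the cognate 7-mer
UGCAUGU) and $K_2$, the competitive binding scheme gives

$$\frac{S_1}{S_2} \;=\; \frac{S_{1,0}}{S_{2,0}}\,
  \frac{1 + E/K_2}{1 + E/K_1},$$

where $S_{i,0}$ are the control-reaction abundances. Writing
$R = (S_1/S_{1,0}) \big/ (S_2/S_{2,0})$ for the ratio of
control-normalized frequencies and expressing concentrations in units of
the reference constant ($K_1 = 1$, $e = E/K_{1/2}^{\mathrm{ref}}$), the
variant's relative dissociation constant is

$$K_{2,\mathrm{rel}} \;=\; \frac{e}{R\,(1+e) - 1},$$

and the reported quantity is its reciprocal, the relative association
constant $K_{A,\mathrm{rel}} = 1/K_{2,\mathrm{rel}}$, so that the
reference is exactly 1 and larger means tighter binding. Note the
normalization must divide by the control *of the same species*: the
inversion above is the algebraically consistent solution of the
competitive scheme (on exact free-fraction inputs it returns
$K^{\mathrm{ref}}/K_v$ to machine precision, a property asserted in the
test suite).

Three numerical details matter:

* **Pseudocount.** All count cells receive +0.5 (the standard
  half-integer correction) before frequencies are formed, so fully
  depleted variants remain computable. A variant absent everywhere ends
  up at a ratio of pseudocounts, i.e. approximately 1.
* **Informative concentrations.** The denominator $R(1+e) - 1$ is, in
  exact data, $e/K_{2,\mathrm{rel}}$: positive whenever the variant is
  detectably bound. Counting noise can push it to or below zero, in
  which case that concentration carries no information for that variant
  and is dropped; a variant with no informative concentration is flagged
  `below_detection`.
* **Aggregation across concentrations.** The default summary is the
  median of per-concentration estimates — robust and directly
  interpretable. It has a known weakness: at the *lowest* protein
  concentrations the depletion of weak binders (a percent or two) sits
  below the counting noise, and those noise-dominated estimates enter
  the median. The package therefore also provides
  `estimator = "global"`, a least-squares fit of the entire
  log-depletion-ratio curve across all concentrations; it weights every
  concentration by its actual signal and is the estimator used in the
  package's own end-to-end validation, where it recovers
  $\ln K_{A,\mathrm{rel}}$ with Pearson $r \approx 0.97$ at the default
  simulation scale. Mean aggregation is also available.

**Choice of the reference constant.** $K_{1/2}^{\mathrm{ref}}$ (default
1.6 nM, the cognate's measured half-saturation constant) only enters by
expressing $E$ in reference units. Its influence on a per-concentration
estimate is $O(K^{\mathrm{ref}}/E)$ in absolute $K_{A,\mathrm{rel}}$
units, so at the top of the default series ($E \approx 19{,}740$ nM, i.e.
$e > 10^4$) a twofold error in the assumed reference constant moves
estimates of detectable variants by well under 1%. Aggregated values for
*weak* binders inherit a larger low-concentration contribution; the test
suite asserts the <1% bound on top-concentration estimates and a few-%
bound on aggregated values in the upper informative decade.

## Binding isotherms for individual substrates

Direct titrations are fit with the exact two-component equilibrium
("quadratic") binding equation

$$\mathrm{FB} = A\,\frac{(K_{1/2}+R_0+P_0) -
  \sqrt{(K_{1/2}+R_0+P_0)^2 - 4 R_0 P_0}}{2 R_0},$$

implemented in the rationalized form
$2AP_0 / \big(s + \sqrt{s^2 - 4R_0P_0}\big)$, which is numerically stable
in the hyperbolic limit $R_0 \to 0$ (where half-saturation occurs exactly
at $P_0 = K_{1/2}$). Competition experiments use

$$\mathrm{FB} = A\,\frac{R_1}{R_1 + K_1\,(1 + R_2/K_2)},$$

with $K_1$ fixed from a direct measurement. Both fits run
Levenberg–Marquardt least squares with multistart ($K$ at 0.1×, 1× and
10× the median nonzero titrant concentration; $A$ at 1) and report
standard errors from the converged fit.

## 5-mer projection and flanking effects

The minimal recognition element is 5 nt, so 7-mer affinities are
projected onto 5-mer space: each 5-mer has up to 3 × 16 = 48 distinct
7-mer contexts (three registers inside the randomized window, 16 flank
combinations; self-overlapping 5-mers such as AAAAA have fewer). The
5-mer summary is the median over contexts (quartiles and whiskers carry
the box-plot view); the mean is available by flag, and registers
extending into the fixed linkers are excluded — which is exactly what
yields the count 48. Flanking-nucleotide effects around a core 5-mer use
the centered register (N-core-N, 16 variants) and report per-flank
medians and log-ratios.

## PWM and pairwise-coupling models

Log relative affinities are modelled by ordinary least squares on
indicator encodings of the sequence:

* **PWM:** one coefficient per (position, nucleotide), with the cognate
  motif (GCAUG for 5-mers, UGCAUGU for 7-mers) as the reference level —
  its nucleotides' coefficients are identically zero. 15 free positional
  coefficients for 5-mers.
* **PWC:** adds one coefficient per (position pair, non-reference
  nucleotide pair): 10 × 9 = 90 interactions for 5-mers. Interaction
  t statistics (coefficient / OLS standard error) above |t| = 3.5 are
  flagged significant, with no multiple-testing correction — the bare
  threshold is the field's convention for these models.

Two modelling decisions deserve explanation. First, "baseline" means two
things at once: reference coding *and* withholding the cognate variant's
data point from the fit. Withholding is what makes the cognate a
diagnosable *outlier* — its out-of-fit residual measures how far the
cognate's affinity exceeds what the additive (or pairwise) model of all
other variants predicts, the package's formalization of a distinct
cognate binding mode. $R^2$ is reported on the fitted set, with a
variant including the withheld point also available. Second, an
intercept is included (toggleable): the reference-encoded row need not
sit at $\ln K_{A,\mathrm{rel}} = 0$ for 5-mer medians. Affinities below
a detection floor (default $10^{-4}$) are clipped before the log
transform, otherwise below-detection variants dominate the fit. A
rank-deficient design (e.g. a table in which some nucleotide never
occurs at a position) is refused with the aliased columns named.

## Distribution analytics

* **Histogram:** 100 equal-width bins over $[0, \max K_{A,\mathrm{rel}}]$
  (a bin *width* of 100 would be meaningless for values ≤ 1, so the
  conventional reading of "bin size 100" as a bin count is used).
* **Bimodality:** one- vs two-component Gaussian mixtures on floored
  $\ln K_{A,\mathrm{rel}}$, compared by BIC (mclust; larger is better).
  The affinity distribution of a highly specific protein is bimodal —
  the minor, high-mean component should collect the cognate-motif
  variants — whereas a nonspecific landscape prefers one component.
  This quantifies what is usually asserted visually.
* **Logo:** position frequency matrix and information content
  ($2 + \sum_b p_b \log_2 p_b$ bits) of the top-40 variants by affinity,
  ties broken lexicographically for reproducibility. No motif-discovery
  E-values are computed.
* **Percentile ranks** use the midrank convention for ties.
* **Specificity ratio:** max/median of normalized affinities — a scale-
  invariant one-number summary of discrimination. RBNS R scores from
  other proteins are first mapped linearly onto $[1, e]$ and natural-log
  transformed onto $[0, 1]$, making the ratio comparable across assays.

## What the simulator emulates — and what it does not

The generator reproduces the experiment's design: the 53-nt construct
(24-nt 5' constant region, randomized 7-mer, 22-nt 3' constant region),
50-nt single-end reads laid out as 2-nt UMI + 3-nt library index + the
constant region (read positions 6–29) + the 7-mer (positions 30–36), the
eight index barcodes, a no-protein control plus seven protein
concentrations log-spaced 20 → 19,740 nM, multinomial sampling of 10^6
molecules per library, geometric PCR duplication, and independent
per-base substitution errors (default 10^-3).

The default ground-truth landscape is two log-normal modes: cognate
variants (those containing GCAUG, or the closely related GCACG) around
3 nM (log-sd 0.5), everything else around 1 µM (log-sd 1.2) — orders of
magnitude apart, with the background mode centred inside the
concentration window so most variants are informative. These are the
conditions under which the package validates itself; they are *choices*,
made once, not measurements.

Deliberate non-features, which bound what passing tests can show about
real data:

* the background mode is *unstructured* — log-affinities of non-cognate
  variants are i.i.d. draws, with no additive sequence dependence. PWM
  and PWC fits on this landscape therefore explain almost no variance;
  the model machinery is instead validated on additively generated
  landscapes (`mode = "additive"`), where exact coefficient recovery is
  asserted. Real landscapes sit in between.
* no RNA secondary structure or masking-oligo imperfections, no reverse
  transcription or gel-purification biases, no index hopping, no
  quality-score information.
* substitution errors inside the randomized window are undetectable by
  construction (the true 7-mer is unknown); they transfer a small
  fraction of reads between variants and are simply accepted verbatim,
  as in the real pipeline.

**UMI saturation.** The 2-nt UMI admits only 16 distinct values, so
UMI-collapsed counts saturate at 16 per variant and library — at the
default depth (~61 molecules per variant in the control) collapse would
destroy quantification. Both raw and UMI-collapsed counts are therefore
reported; quantification defaults to raw counts and a warning fires when
a substantial fraction of occupied cells is near the ceiling.

## Problem sizes and determinism

The package's own validation simulates the full 16,384-variant library
at 8 concentrations and 10^6 reads per library (about half a minute),
plus lighter integration runs at 2 × 10^5 reads; model-recovery checks
use 20 seeded replicates of the 1,024-variant 5-mer table. All
stochastic steps are seed-controlled: landscapes through
`make_landscape(seed=)`, the read-level simulation through
`simulation_config(seed=)` (library *j* uses `seed + j`, keeping
libraries independent yet reproducible).

## Known limitations

* The assay yields *relative* affinities only; absolute calibration of
  all variants is out of scope, and the reference constant enters only
  as a unit.
* The median estimator is biased for weak binders when low, uninformative
  concentrations dominate; use `estimator = "global"` for full-range
  work.
* The bimodality test compares exactly one against two Gaussian
  components; it is a model comparison, not a nonparametric mode count.
* Mixture membership, logos and percentile ranks operate on point
  estimates and ignore per-variant uncertainty.
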