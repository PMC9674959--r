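---
title: "Protein-specific variant effect prediction for the carnitine transporter OCTN2: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-specific variant effect prediction for OCTN2: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octnvep)
```

## The problem

OCTN2 (encoded by *SLC22A5*) is the plasma-membrane sodium-dependent
carnitine transporter; biallelic loss-of-function (LOF) variants cause
Carnitine Transporter Deficiency (CTD), an autosomal recessive inborn error
of metabolism that is treatable when caught early. Most cataloged OCTN2
missense variants lack a clinical interpretation, so a protein-specific
predictor — trained on in-vitro uptake measurements of ancestrally diverse
variants — is a practical route to interpreting novel variants of uncertain
significance.

This package implements that analysis as a reusable pipeline:

1. **Assay stage** — raw radiolabeled-carnitine uptake replicates are
   normalized to percent-of-wild-type function, tested against wild type,
   and called LOF below a 20% threshold.
2. **Featurization** — each missense variant is described by sequence-,
   structure-, and prediction-based features, scaled to [0, 1].
3. **Modeling** — L1-penalized logistic (classification) and linear
   (regression) models, evaluated by repeated random subsampling, with a
   binarizing cutoff chosen to maximize sensitivity + specificity.
4. **Saturation** — the classifier scores all 19 × L possible missense
   variants on a normalized 0–1 functional scale.
5. **Population genetics** — LOF allele frequencies are pooled per
   population into minimum carrier-frequency estimates.
6. **Synthetic data** — a generator emulates a complete characterization
   study with known ground truth, so every stage is testable without any
   external download.

## Assay model

Each variant is measured in technical triplicate wells across three
biological replicates, alongside the same batch's wild-type (WT) and
empty-vector (EV) controls. Function is

$$\%WT = 100 \cdot \frac{\text{Variant} - \text{EV}}{\text{WT} - \text{EV}},$$

which is invariant to a shared additive background and may legitimately
fall below 0 or above 100; such values are retained, never clipped.
Technical wells are averaged *within* each biological replicate first, then
mean and SEM are taken across biological-replicate means — with unbalanced
wells this differs from a pooled mean, and the replicate hierarchy is the
meaningful unit of variation. Each per-replicate mean is normalized against
batch-level control means, so WT itself reads 100 ± replicate noise and the
variant-vs-WT comparison is a two-sample t test on normalized replicate
values. The paper-scale Bonferroni level for 150 simultaneous tests is
0.05/150 ≈ 3.3 × 10⁻⁴. The classical equal-variance Student test is the
default, with Welch available by argument; whether the original tests were
run on raw counts or normalized values is not documented in our sources, so
both code paths exist and the normalized-value route is the default.

A variant is LOF when its mean function is **strictly below 20%** of WT —
the boundary value 20.0 is *not* LOF. The threshold is an argument
everywhere it is used.

Cohort summaries follow standard practice: ancestry-group comparisons use
one-way ANOVA with Tukey HSD post hoc (delegated to base R's `aov` and
`TukeyHSD`), and localization-class comparisons use Welch's ANOVA
(`oneway.test`) with Games–Howell post hoc pairwise tests, which assume
neither equal variances nor equal group sizes. Games–Howell is implemented
here directly (Welch-type standard errors and degrees of freedom against
the studentized-range distribution) and is verified in the test suite
against an independent implementation's output frozen to three decimals.

## Feature sets

* **Sequence set** — residue position; indicator features for the five
  region classes (N-terminus, transmembrane, extracellular loop,
  intracellular loop, C-terminus) and for each of the 25 individual
  topological regions; Kyte–Doolittle hydropathy change (alt − ref); net
  side-chain charge change at pH 7 (His treated as neutral); residue
  volume change (Zamyatnin); BLOSUM62 substitution score; indicators for
  proline introduced and glycine removed. Sequence features depend only on
  (position, ref, alt, topology) — never on assay outcomes, so no label
  leakage is possible by construction.
* **Structure set** — per-residue model confidence (pLDDT, read from the
  B-factor column of AlphaFold-style PDB files); contact number (Cα
  neighbors within 10 Å, a documented constant); relative burial (contact
  number normalized to the maximum observed); and distance to the
  protein's principal centroid axis, a generic proxy for proximity to a
  transporter's translocation pore.
* **Prediction set** — per-variant scores from external unsupervised
  predictors, joined by variant label. These are consumed as score tables,
  never recomputed.
* **Combined** — the union of the three.

The exact feature list used in the original study is in supplementary
material we do not redistribute; the registry above realizes the same
categories and is deliberately editable.

**Scaling.** Every feature is min–max scaled to [0, 1] so that penalized
coefficients are directly comparable. Scaling is fitted on the *training
rows of each evaluation split only* and then applied to the held-out rows
(values outside the training range are clipped to [0, 1]) — fitting on all
rows before splitting would leak test information. Constant columns scale
to 0 (not NaN) and are reported; the L1 penalty zeroes them anyway. A
missing external score is imputed at the training-column mean, with a
companion 0/1 missingness-indicator column, keeping all variants in the
model rather than dropping rows.

## Penalized models and the evaluation protocol

The classifier minimizes the mean negative log-likelihood of the logistic
model plus $\lambda \sum_j |\beta_j|$ (intercept unpenalized); the
regression model minimizes $\tfrac{1}{2n}\mathrm{RSS} + \lambda
\sum_j|\beta_j|$. Both are solved by coordinate descent (IRLS outer loop
for the logistic case) implemented in compiled code, with deterministic
feature ordering, warm starts along a decreasing λ path, an active-set
sweep strategy, and convergence declared when the largest weighted squared
coefficient update falls below 10⁻⁷ (10⁻¹⁴ for final single-λ fits). This
criterion tolerates the exactly-collinear indicator blocks the feature set
contains (each region-class indicator is the sum of its per-region
indicators), where the L1 solution is non-unique but predictions are not.
The test suite pins the solver to three oracles: unpenalized `glm`/`lm`
fits at λ = 0 (to 10⁻⁴/10⁻⁶), an independent penalized implementation
along the path, and a prediction-equivalence check under column
duplication. A saturated path (> 99.9% of null deviance explained) is
terminated early and carried forward.

**Penalty tuning** is 5-fold × 5-repeat stratified cross-validation over a
grid of 50 log-spaced λ values (three decades below the smallest
all-zeroing λ), maximizing mean held-out AUC for classification and R² for
regression; exact ties resolve to the larger λ (sparser model). The inner
criterion (AUC rather than accuracy) is a documented choice.

**Repeated random subsampling** is the outer protocol: for each iteration a
stratified train/test split (stratified by LOF label — plain random splits
at n = 150 with ~25% prevalence too often produce degenerate folds), with
scaling fitted on train, λ tuned on train, the model fitted on train, the
binarizing cutoff selected **on training scores** by maximizing
sensitivity + specificity over all midpoints between adjacent sorted
unique scores (± infinite sentinels, ties to the smallest cutoff), and the
metric suite evaluated on the held-out rows at that cutoff. Choosing the
cutoff on test scores would leak; the leak-free variant is the default and
only route. Split sizes follow the study design: 80/20 for model
selection, 70/30 (105/45 of 150) for the final classifier report, and
110/40 for regression. Reports are bit-reproducible given the master seed,
which expands counter-style into per-iteration seeds.

Metrics use LOF as the positive class throughout: sensitivity,
specificity, PPV, NPV, accuracy, MCC from the confusion matrix at the
cutoff (a zero-denominator metric is reported missing, never 0), and AUC
via the rank (Mann–Whitney) statistic with midrank ties — equal to the
trapezoidal area under the empirical ROC, and invariant to monotone score
transforms. Published comparisons of predictors sometimes swap PPV/NPV
conventions between rows; fixing the positive class and documenting it
avoids that ambiguity.

**Model grid.** Three model types (penalized model, random forest,
gradient boosting) × four feature sets are each evaluated with the same
protocol and ranked by mean test AUC. The tree ensembles enter through a
generic fit/predict contract and are delegated to `randomForest` and
`xgboost` with fixed, documented default hyperparameters (500 trees; 100
rounds, learning rate 0.1, depth 3) — the comparison protocol, not the
ensembles, is the contribution here.

**Feature importance** summarizes the per-iteration LASSO coefficients:
median, IQR, Tukey-style whiskers, and the fraction of folds with a
nonzero coefficient — comparable across features because inputs were 0–1
scaled.

**Localization.** Localization is three-class (membrane / mixed /
intracellular), and two one-vs-rest classifiers are trained with the same
protocol: full membrane localization vs the rest, and full intracellular
retention vs the rest. The mixed class makes a single binary split
ill-posed; the two models answer the two clinically distinct questions.

## Saturation scoring

`enumerate_missense()` produces all 19 substitutions at every position
(10,583 for the 557-residue transporter). The classifier's LOF probability
*p* is mapped to a normalized functional score

$$s = \begin{cases} 0.5 + 0.5\,(c - p)/c & p \le c\\
0.5 - 0.5\,(p - c)/(1 - c) & p > c \end{cases}$$

where *c* is the selected cutoff: a piecewise-linear calibration that is
continuous, strictly decreasing, maps 0 → 1 and 1 → 0, and places the
decision boundary exactly at 0.5, so *s* > 0.5 is identical to *p* < *c*.
Only the boundary semantics of 0.5/0/1 are externally specified; this map
is the simplest consistent convention and is documented as such. The
heatmap export orders substitutions by the alphabetical one-letter code
and leaves reference cells missing.

## Carrier frequencies

For a population, the allele frequencies of the LOF variants are pooled
into $q = \sum \mathrm{AF}$ and converted to the Hardy–Weinberg
heterozygote frequency $2q(1-q)$, reported as "1:N" with
$N = \mathrm{round}(1/\mathrm{carrier\ freq})$. The simpler $2q$
approximation is available by argument; at the $q \lesssim 0.003$ typical
of rare variants the two differ negligibly. A variant with no recorded
frequency in a population contributes 0 — which is exactly why the
estimates are minima.

## The synthetic-study generator

`simulate_study()` draws a topology-matched random protein (TM segments
enriched in hydrophobic residues), a compact globular coordinate model (a
confined random walk at protein-like packing density, so burial and
centroid-axis distance vary across residues — an ideal helix would give
every interior residue the same contact count and leave the planted
structural effect invisible), and a latent liability $\ell = \beta_0 + x^\top\beta^*$ over the 0–1 scaled
sequence+structure features of the *full enumeration*. True function is
$120 \cdot \mathrm{logit}^{-1}(-\ell)$ — the 120-logistic scale keeps
values in a realistic range with tails slightly outside [0, 100], as real
uptake data show (variants can sit below background or above WT). The
intercept is calibrated on the enumeration quantile so that a uniformly
drawn variant is LOF (< 20%) with probability 0.25, the approximate
prevalence of the real characterized set; each study of n = 150 then
scatters binomially around that target.

Default conditions: n = 150 variants on L = 557 (both configurable; tests
use a fast L = 60 / n = 40 profile); 3 biological × 3 technical
replicates; replicate noise of 8 (biological) and 4 (technical) %WT units;
wells generated by inverting the normalization formula around batch
controls (EV 50, WT 550 counts/µg). Plate batches are assigned at random:
the sampled variants are position-sorted, and a position-ordered plate
layout would confound shared-control noise with positional features.
Localization is cut from the same true function (< 30% intracellular,
> 62% membrane, mixed between) with a 10% label-noise rate — encoding the
observation that localization associates with, but does not determine,
function. Eight ancestry-style groups include a 10-variant clinical
analogue enriched for LOF by weighted sampling; population-exclusive
groups carry allele frequencies only in their own population, drawn from
an exponential of mean 2 × 10⁻⁴ truncated below 0.01 (all variants rare).
External-predictor-style score tables are noisy logistic transforms of the
same liability (SD 0.15). The true coefficient vector is sparse and
strong — transmembrane location (+2), BLOSUM62 (−2.5), centroid-axis
distance (−2: pore-proximal substitutions damaging), proline introduction
(+1.5) on the 0–1 scale — a truth detectable at n = 150, so
parameter-recovery tests are well-posed. Contact number and relative
burial are affinely identical after 0–1 scaling, so no effect is planted
on that collinear pair; the fitted model may split weight between them
freely without changing predictions.

What the generator does **not** emulate: a real protein fold (the
globule stand-in only feeds contact/burial/axis features), real mutation or
site-frequency spectra, plate-position artifacts, or the correlated errors
of real external predictors. Passing tests therefore demonstrate that the
pipeline's statistics behave as designed under its own assumptions — not
that the trained model generalizes to real OCTN2 data, which requires the
real characterized set.

## Packaged fixtures

The repository cannot redistribute the canonical OCTN2 sequence or its
curated topology, so `inst/extdata/` ships a clearly labelled *synthetic*
stand-in at the correct scale: a 557-residue sequence generated by the
topology-aware sampler, and a 25-region map (intracellular N/C termini, 12
TM segments, 6 extracellular and 5 intracellular loops, including the two
very short extracellular loops of 4 and 3 residues and the long first
extracellular and third intracellular loops characteristic of this
transporter family). Every scale-dependent check (19 × 557 = 10,583
enumerated variants; 150/557 ≈ 0.27 overall density; 25 regions) is exact
on the stand-in; residue-identity-dependent results are not, and no test
pretends otherwise. Replacing the two fixture files with the real sequence
and topology runs the identical pipeline on the real protein.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full protocol at the
study's own scale — 100 subsampling iterations at n = 150 with 5 × 5 inner
cross-validation over 50 λ values, and 50 independent synthetic studies
for recovery checks; the model-selection grid driver defaults to 25
iterations per cell with the headline report at 100. Degenerate inputs are
defined errors, not silent results: single-class labels, non-finite
features, WT signal at or below background, constant response for R²,
cutoffs outside (0, 1), pooled q ≥ 1, incomplete saturation tables, and
duplicate variant labels or score-table keys all raise immediately.

## Known limitations

* The packaged sequence/topology are synthetic stand-ins (above).
* Real external predictor scores and the original per-variant tables are
  not redistributed, so the original study's headline performance on the
  real characterized set cannot be recomputed from this repository; the
  simulation acceptance targets calibration and recovery properties
  instead.
* The t-test's exact data basis (raw vs normalized, pairing) in the
  original study is unknown; both routes are provided.
* Carrier-frequency pooling assumes Hardy–Weinberg equilibrium and
  independence of the pooled variants; compound heterozygosity and
  penetrance are out of scope.
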