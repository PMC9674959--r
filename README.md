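# octnvep

Protein-specific missense variant effect prediction for the carnitine
transporter OCTN2 (*SLC22A5*), whose biallelic loss-of-function (LOF)
variants cause Carnitine Transporter Deficiency (CTD) — a treatable but
potentially fatal inborn error of metabolism. Most cataloged OCTN2
missense variants have no clinical interpretation; this package implements
the analysis that turns an in-vitro uptake characterization campaign into
a protein-specific predictor for all possible missense variants, for
researchers doing functional genomics of membrane transporters.

## What it computes

**Assay stage.** Raw radiolabeled-carnitine uptake replicates are
normalized against batch wild-type (WT) and empty-vector (EV) controls,

    %WT = 100 · (Variant − EV) / (WT − EV),

averaged technical-then-biological, tested against WT (two-sample t test,
Bonferroni α = 0.05/n), and called **LOF when %WT < 20** (strict). Cohort
summaries: per-topology-region characterization density, function by
ancestry group (ANOVA + Tukey HSD), function by subcellular localization
class (Welch ANOVA + Games–Howell).

**Model.** An L1-penalized logistic regression on topology-aware features
scaled to [0, 1],

    min  (1/n) Σᵢ log(1 + e^{ηᵢ}) − yᵢ ηᵢ  +  λ Σⱼ |βⱼ| ,   η = β₀ + xᵀβ,

solved by coordinate descent in compiled code, with λ tuned by 5×5
stratified cross-validation on AUC. Evaluation uses repeated random
subsampling (stratified splits; scaling and tuning inside each training
fold; binarizing cutoff maximizing sensitivity + specificity on training
scores), reporting AUC, accuracy, sensitivity, specificity, PPV, NPV and
MCC as mean ± SD over iterations. A model grid (penalized model / random
forest / gradient boosting × sequence / structure / prediction / combined
feature sets) ranks combinations by mean test AUC. A parallel penalized
linear model predicts quantitative %WT function (R²), and two
one-vs-rest classifiers predict full membrane localization and full
intracellular retention.

**Saturation + population genetics.** The classifier scores all 19 × L
possible missense variants; LOF probabilities are mapped to a normalized
functional score in [0, 1] with the decision cutoff pinned at 0.5
(score < 0.5 = predicted severe LOF). Population LOF allele frequencies
are pooled (q = ΣAF) into minimum carrier-frequency estimates
2q(1 − q), reported as "1:N".

**Synthetic studies.** `simulate_study()` generates a complete
characterization campaign with known ground truth (sequence, 25-region
topology, raw wells, localization, ancestry groups, allele frequencies,
external-style predictor scores), so the entire pipeline runs and is
tested without any external data. The packaged 557-residue sequence and
topology under `inst/extdata/` are clearly labelled synthetic stand-ins
at the real protein's scale.

## Worked example

The analysis is organized as numbered drivers under `analysis/`:

```sh
Rscript analysis/01_simulate.R 1     # synthetic study  -> results/study/
Rscript analysis/02_assay.R          # %WT, LOF calls, cohort summaries
Rscript analysis/03_featurize.R      # four feature sets
Rscript analysis/04_train_evaluate.R # model grid, final classifier, regression, localization
Rscript analysis/05_saturation.R     # all-possible-variant predictions
Rscript analysis/06_carriers.R       # per-population carrier frequencies
```

A run with seed 1 prints, among other things:

```
Characterized 150 variants: function -8.5 .. 104.2 %WT
  LOF (<20%): 49 (32.7%); significant vs WT at alpha=3.3e-04: 60
  overall characterization density: 0.27 (per-region 0.00 .. 0.67)
  localization medians: membrane 78.4 / mixed 43.1 / intracellular 16.5 %WT (Welch p = 6.8e-24)

== final LOF classifier: 100 x 70/30 subsampling ==
evaluation_report: 100 iterations of penalized ( 105 train / 45 test )
  auc          0.926 +/- 0.038
  accuracy     0.846 +/- 0.057
  sensitivity  0.844 +/- 0.117
  specificity  0.847 +/- 0.075

top features by |median coefficient|:
            feature median  iqr frac_nonzero
           class_TM  3.561 1.16         1.00
           blosum62 -2.328 1.33         0.98

Scored 10583 possible missense variants (557 residues x 19)
  predicted severe LOF (score < 0.5): 3685 (34.8%)

Minimum carrier-frequency estimates from 49 LOF variants:
  African    q = 2.19e-03  carrier 1:229
  EastAsian  q = 4.01e-03  carrier 1:125
```

Reading it: 150 synthetic variants span the full functional range with
below-background and above-WT tails; about a quarter to a third are LOF
(the design prevalence is 25%, and each study of 150 scatters around it);
the classifier separates LOF from functional variants with held-out AUC
near 0.93 under the generator's default signal-to-noise, and the features
it ranks highest are exactly the planted truth (transmembrane location,
substitution severity, proline introduction, pore proximity); the
saturation table scores every possible substitution; pooled LOF allele
frequencies translate into per-ancestry carrier-frequency minima. Numbers
vary with the seed; rerunning with seed 1 reproduces them exactly.

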