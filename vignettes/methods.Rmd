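---
title: "Feature-based neoepitope immunogenicity prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based neoepitope immunogenicity prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neopredict)
```

## The problem

Tumor-specific mutations create neopeptides, a small minority of which
are recognized by patient T cells. In multimer-based screens only
about 2-3% of pre-filtered candidates (eluted-ligand percentile rank
below 2, expressed transcript) turn out immunogenic. Selecting
candidates for vaccines or cell therapy therefore depends on ranking
quality in the extreme low-prevalence regime, which is why this
package evaluates with the *partial* AUC at a false-positive rate of
0.1 (AUC01) alongside the global AUC, and with per-patient top-20/50
capture -- the quantity a treating team actually cares about.

`neopredict` implements the full modeling pipeline around a
feature-based random-forest classifier: descriptor computation,
leakage-aware partitioning, class-balanced ensemble training,
evaluation, and survival stratification by predicted neoepitope load.
A synthetic screen generator with planted signal makes every stage
testable without access to patient data.

## The descriptor panel

Each candidate record carries the mutant peptide (8-12 residues), its
wild-type counterpart (absent for frameshifts), the predicted 9-mer
MHC binding core, and externally predicted columns (NetMHCpan-style
eluted-ligand and binding-affinity percentile ranks, stability, PRIME,
foreignness, expression, variant allele fraction, cellular prevalence,
priority score) that this package consumes but does not compute.

Sequence-derived descriptors:

* **HydroAll / HydroCore** -- mean Kyte-Doolittle hydropathy of the
  full peptide and of the *non-anchor subsequence*, core positions 4-8
  (`nonAnchorSubsequence()`). Anchors (core positions 2 and 9) face
  the MHC groove; positions 4-8 face the T-cell receptor. The
  hydropathy scale is configurable; Kyte-Doolittle is the default
  because it is the field's standard general-purpose scale.
* **PropHydroAro** (V,I,Y,F,W,L over the full peptide), **Aro**
  (F,W,Y, full peptide), and **PropAro / PropSmall / PropAcidic /
  PropBasic** over the non-anchor window. "Small" is not a universally
  fixed set; we default to the Taylor classification
  {A,G,S,T,C,P,N,D}, configurable.
* **CysRed** -- the count of cysteines (configurable to a proportion;
  the count is the default because cysteine-mediated artifacts scale
  with the number of reactive thiols, not their fraction).
* **Inst** -- the Guruprasad instability index, `(10/L) * sum` of the
  published DIWV dipeptide weights.
* **pI** -- isoelectric point by bisection (tolerance 1e-4 pH units)
  on the Henderson-Hasselbalch net charge with the EMBOSS pKa set.
  The charge is strictly decreasing in pH, so bisection on [0, 14]
  always converges.
* **mw** -- average molecular weight from standard residue masses.
* **DAI** -- differential agretopicity, `rank_el_wt - rank_el_mut`.
  With this orientation a *positive* DAI means the mutation improved
  predicted presentation. The sign is a flag
  (`dai(..., wt_minus_mut = FALSE)`); AUC magnitude is unaffected by
  orientation.
* **SelfSim** -- a normalized BLOSUM62 string kernel
  `K(mut, wt) / sqrt(K(mut,mut) K(wt,wt))` summing substitution-score
  products over all aligned k-mer pairs, k = 1..3. Identical
  sequences score exactly 1. The kernel depth and matrix are
  pluggable; this is the standard peptide kernel of the epitope
  literature.

For 8-mers the predicted core contains an inserted position, which the
caller encodes as `X`; it contributes 0 to scale means and is excluded
from class proportions.

Mutation-context and patient-level covariates:

* **ValMutRNACoef** = `n_variant / (n_coverage + 100)` -- the damped
  proportion of variant-supporting RNA reads; the +100 keeps poorly
  covered positions near zero.
* **CYT** -- geometric mean of GZMA and PRF1 TPM, with a 0.01
  pseudocount so a single zero transcript does not annihilate the
  score (disable with `pseudocount = 0`).
* **Population scores / MCPmean** -- per-population means of
  log2(TPM+1) over marker genes, averaged into one per-patient
  scalar. The package ships an *illustrative* two-marker panel for the
  ten canonical immune/stromal populations; for real data supply the
  marker list of your deconvolution tool. Only the per-patient mean
  feeds the model, which makes the feature robust to the exact panel.
* **HLAexp** -- summed TPM of HLA-A/B/C (mean available via a flag;
  the sum is the default since total class-I dosage is what antigen
  presentation sees).

## Feature sets

`featureSet("standard")` is the 22-feature default model. Relative to
the full descriptor panel it excludes the one-hot mutation consequence
and position categories (computed, but they add no predictive power in
a forest that already sees the continuous descriptors), `HydroAll` and
`VarAlFrac` (each nearly duplicated by `HydroCore` and `PrioScore`
respectively), and `Aro` (the same residue class as `PropAro`, counted
over a wider window). `featureSet("simple")` further drops `PrioScore`
and `CelPrev`, the genomics-derived columns typically unavailable on
external benchmark data. `featureSet("tme")` adds `CYT`, `MCPmean`,
`HLAexp`.

## Assembly, imputation, feature deselection

`assembleFeatureTable()` joins the three layers into a `FeatureTable`
(peptides x features, with labels and per-feature missingness). Rank
columns of frameshift peptides, patients without RNAseq and similar
gaps stay `NA` and are mean-imputed -- always with means computed on
the *training* rows only (`imputeMean(train, apply)`), so no test
statistic leaks into training.

`correlationFilter()` removes redundant features: while any pair of
retained features has |Spearman rho| >= 0.7, the member with the lower
univariate AUC01 against the labels is dropped (strongest correlation
resolved first; the criterion is switchable to full AUC; name-order
tie-break makes the result independent of column order). The filter
runs inside each cross-validation fold on that fold's training rows.

## Leakage-aware partitioning

Public epitope motifs and patient effects both leak across naive
random folds. `assignPartitions()` therefore builds a patient graph
whose edges join patients owning immunogenic peptides that share any
identical 6-mer (`sharesMotif()`), takes connected components, and
distributes components over 5 folds greedily by peptide count.
Non-immunogenic peptides inherit their patient's fold. Motif length 6
is the default: long enough that unrelated 8-12-mers rarely collide
(a specific 6-mer has a frequency of about 20^-6 per position), short
enough to merge near-identical variants; it is configurable. Before
training each fold, any training peptide whose mutant sequence occurs
verbatim in the test fold is removed (`dedupTrain()`).

## The balanced ensemble

With ~2.7% positives a single forest mostly learns to say "no".
`trainBalancedEnsemble()` instead fits `n_subsamples` probability
forests (default 50, hyperparameters: 2,000 trees, depth 6, minimum
leaf 6), each on *all* training positives plus an independent draw of
500 negatives (without replacement within a draw; when fewer than 500
negatives exist, each draw uses all of them and says so). The ensemble
score is the arithmetic mean of the forests' positive-class
probabilities -- probabilities rather than ranks, because mean
probabilities keep the score scale interpretable across ensembles; no
calibration is applied. Each subsample index gets its own RNG stream
derived from the configuration seed, so runs are exactly reproducible
(forests are fitted single-threaded for the same reason).

The hyperparameters are fixed by design, so the "nested" part of the
cross-validation reduces to per-fold feature selection and imputation;
no inner hyperparameter loop is implemented.

Impurity-based feature importances are normalized to sum to one within
each forest, averaged over a fold's forests, then over folds, with
deselected features contributing zero (`featureImportance()`).

Two profiles exist: `ensembleConfig("full")` (50 x 2,000 trees, the
fidelity setting) and `ensembleConfig("test")` (10 x 200 trees), which
preserves behavior at a fraction of the cost and is what the test
suite and the worked examples use.

## Evaluation conventions

* **AUC01** is the *unnormalized* area under the ROC curve restricted
  to FPR in [0, 0.1], with linear interpolation at the window edge:
  a perfect classifier scores 0.1, the chance diagonal 0.005. This
  matches the magnitudes conventionally reported for this metric
  (e.g. values like 0.013 for single features); a McClish-normalized
  variant is available behind `normalized = TRUE`.
* **Orientation is explicit everywhere.** Percentile-rank predictors
  are better when *low*; every evaluation function takes
  `higher_is_positive` so RankEL can be evaluated as a classifier
  without ad-hoc sign flips.
* The decision cutoff is the candidate threshold (observed scores plus
  midpoints) minimizing |sensitivity - specificity|, ties broken
  toward higher specificity; a score equal to the cutoff counts
  positive. From the resulting confusion matrix, `mcc()` (zero by
  convention when a marginal is empty) and `accuracy()`.
* `delongTest()` implements the DeLong covariance estimate for paired
  AUC differences (two-sided normal p; p = 1 for identical score
  vectors). It agrees with `pROC::roc.test` to machine precision and
  with a 10,000-rep paired bootstrap within 0.02, both asserted in the
  test suite.
* `perPatientTopK()` reports, per patient, the fraction of that
  patient's immunogenic peptides ranked in its top k candidates, with
  deterministic id-order tie-breaks.

## Survival stratification

`neoepitopeLoad()` counts, per patient, peptides passing the cutoff;
`quantileGroups()` splits patients at the type-7 quartiles (R's
default, matching an R-based analysis): high at or above Q3, low at or
below Q1, medium-high strictly between Q2 and Q3, medium-low above Q1
up to Q2. Both boundary quantiles claim equality, so when quartiles
coincide the precedence is high, then low, then the middle groups.
Kaplan-Meier curves and the log-rank test wrap the survival package;
the high-vs-low hazard ratio is a single-binary-covariate
proportional-hazards fit by Newton iteration on the Breslow partial
likelihood, verified against `survival::coxph` to 1e-4.

## The synthetic screen

`generateCohort()` emulates the structure of a multi-patient multimer
screen: 30 patients, 100-400 candidates each, lengths 8:9:10:11 in
proportions 10:60:20:10 (the class-I ligand length bias), uniform
residue frequencies (human-proteome frequencies optional), central
9-mer cores, 10% frameshifts, external prediction columns drawn from
log-normal/beta families with the rank-below-2 pre-filter and the
two-peak strong/weak binder structure enforced. Labels follow a
logistic model on cohort-standardized covariates with planted
coefficients (defaults: HydroCore 1.0, PropHydroAro 0.7, log RankEL
-0.7, CelPrev 0.4, patient CYT scalar 0.8 -- chosen once to give
single-feature AUCs in the 0.6-0.8 range observed for the strongest
real descriptors) and the intercept solved so the expected positive
rate is 2.7%. A tenth of immunogenic sequences are duplicated into
other patients to exercise motif clustering. Survival times are
exponential with rate decreasing in the patient's true immunogenic
count, 70% event rate.

What the generator does *not* emulate: HLA-specific binding motifs,
real covariance between the external predictors, label noise from
incomplete T-cell repertoires, cohort effects. Passing tests therefore
demonstrate that the machinery recovers planted structure under
realistic sizes and prevalence -- not that any particular AUC carries
over to real screens.

The test suite exercises the pipeline at these sizes: a ~1,000-peptide
/ 30-patient cohort for partitioning invariants, 20 x 100 peptides
for null calibration (ten patient-stratified label permutations,
expecting chance-level CV AUC), and 30 x 200 peptides (ten seeds) for
signal recovery, all under the test ensemble profile.

## Known limitations

* Because every balanced draw pairs *all* training positives with a
  fixed 500 negatives, the ensemble's score scale rises with the
  training fold's positive count. Pooling out-of-fold scores across
  folds is therefore slightly miscalibrated when positives are very
  unevenly distributed over folds; per-patient load counts against a
  single pooled cutoff inherit this. Within-fold rankings -- and hence
  per-fold AUCs, per-patient capture, and importance -- are
  unaffected. With many patients per fold the shift shrinks; an
  explicit cross-fold calibration is deliberately not applied.
* The marker panel behind `MCPmean` is illustrative, not the published
  list of any deconvolution tool.
* External predictors are pass-through columns; the package neither
  runs nor approximates them.
* One-hot mutation descriptors are computed
  (`mutationPosition()`, `classifyBinder()`) but excluded from the
  default model.
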