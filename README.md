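# neopredict

Feature-based prediction of neoepitope immunogenicity.

## The problem

Tumor mutations give rise to neopeptides, and a small minority of them
— typically 2–3% of candidates that already pass the standard
pre-filter (NetMHCpan eluted-ligand percentile rank < 2, expressed
transcript) — are actually recognized by the patient's CD8+ T cells.
Screens that test hundreds of candidates per patient with barcoded
peptide–MHC multimers produce exactly the data needed to learn what
distinguishes the immunogenic few, but exploiting such data safely
requires care: shared epitope motifs and patient effects leak across
naive cross-validation folds, and the extreme class imbalance defeats
an off-the-shelf classifier.

`neopredict` is for computational immunologists building or evaluating
neoepitope prioritization on screen-style data. It implements:

* the descriptor panel of such screens — peptide physicochemistry on
  the MHC binding core (mean Kyte–Doolittle hydropathy of core
  positions 4–8, residue-class proportions, instability index,
  isoelectric point, molecular weight), differential agretopicity
  `DAI = RankEL(wt) − RankEL(mut)`, a normalized BLOSUM62 k-mer kernel
  self-similarity `K(mut,wt)/√(K(mut,mut)K(wt,wt))`, the RNA variant
  support coefficient `n_var/(n_cov+100)`, and patient-level tumor
  microenvironment covariates (CYT = √(GZMA·PRF1), mean marker-gene
  population abundance, HLA class-I expression);
* leakage-aware 5-fold partitioning: all peptides of a patient stay
  together, patients sharing an immunogenic 6-mer motif stay together,
  and training rows duplicating a test-fold sequence are removed;
* a class-balanced ensemble: 50 random forests (2,000 trees, depth 6,
  minimum leaf 6), each trained on all positives plus an independent
  draw of 500 negatives, scores averaged;
* evaluation in the low-prevalence regime: unnormalized partial AUC at
  FPR 0.1 (AUC01, perfect = 0.1, chance = 0.005), DeLong paired AUC
  comparison, the sensitivity/specificity-intersection cutoff,
  MCC/accuracy, and per-patient top-20/50 capture;
* survival stratification of patients into load quartiles with
  Kaplan–Meier/log-rank and a high-vs-low proportional-hazards ratio;
* a synthetic screen generator with planted, sequence-linked signal so
  the whole pipeline is testable end to end.

## Worked example

```r
library(neopredict)

## descriptors for a single record
rec <- data.frame(peptide_id = "pep1", patient_id = "P01",
                  mut_seq = "KVAELVHFL", wt_seq = "KVAELVHFI",
                  core9 = "KVAELVHFL", core_start = 0L, label = 1L,
                  rank_el_mut = 0.25, rank_el_wt = 1.8)
round(computePeptideFeatures(rec)[
  c("HydroCore", "PropHydroAro", "SelfSim", "DAI", "Inst", "pI", "mw")], 3)
#>      HydroCore PropHydroAro SelfSim  DAI    Inst   pI      mw
#> pep1      0.82        0.556   0.896 1.55 -12.067 7.55 1055.27

## a synthetic 20-patient screen, end to end
cohort <- generateCohort(syntheticConfig(n_patients = 20,
          peptides_per_patient = c(100, 100), seed = 42))
table <- assembleFeatureTable(cohort$records, cohort$profiles,
                              cohort$rna_counts)
table
#> FeatureTable: 2000 peptides x 28 features (20 patients)
#>   positives: 49 (2.5%)
#>   columns with missing values: 2 (max 9.4%)

parts <- assignPartitions(cohort$records, n_folds = 5)
cv <- crossValidate(table, parts, ensembleConfig("test", seed = 42))
sc <- cvScores(cv)
roc <- rocCurve(sc$score, sc$label)
sprintf("CV AUC %.3f, AUC01 %.4f", roc$auc, roc$pauc01)
#> "CV AUC 0.762, AUC01 0.0260"
head(featureImportance(cv), 3)
#>         feature importance
#> 6     HydroCore 0.16954124
#> 14 PropHydroAro 0.10758039
#> 16       RankBA 0.06942883
```

The cross-validated model recovers the planted core-hydrophobicity
signal as the top-ranked feature and clearly beats the rank-only
baseline (`rocCurve(rank_el, labels, higher_is_positive = FALSE)`
gives AUC 0.639, AUC01 0.0079 on the same peptides): exactly the
qualitative behavior expected when sequence features carry signal
beyond predicted presentation. `ensembleConfig("test")` is the
reduced 10 × 200-tree profile; use `ensembleConfig("full")` for the
50 × 2,000-tree fidelity setting.

A thin command-line wrapper with `simulate`, `featurize`, `partition`,
`cv`, `evaluate`, `survive` and `pipeline` subcommands is installed at
`inst/scripts/neopredict`.

## Vignette

`vignettes/methods.Rmd` documents the model, its assumptions, every
tunable parameter with its default and rationale, the synthetic
generator's scope, and known limitations.
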