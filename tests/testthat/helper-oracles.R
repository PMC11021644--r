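# Independent oracles used to verify the package implementations.
# These deliberately use brute force / different algorithms than the
# functions they check.

# exhaustive pos-neg pair counting (Mann-Whitney form of the AUC)
oracle_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# brute-force k-mer kernel: explicit double loop over all k-mer pairs,
# multiplying substitution scores position by position
oracle_kernel <- function(a, b, k_max, submat) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  total <- 0
  for (k in seq_len(k_max)) {
    if (length(ca) < k || length(cb) < k) next
    for (i in seq_len(length(ca) - k + 1)) {
      for (j in seq_len(length(cb) - k + 1)) {
        p <- 1
        for (d in 0:(k - 1)) p <- p * submat[ca[i + d], cb[j + d]]
        total <- total + p
      }
    }
  }
  total
}

oracle_self_similarity <- function(a, b, k_max, submat) {
  oracle_kernel(a, b, k_max, submat) /
    sqrt(oracle_kernel(a, a, k_max, submat) *
           oracle_kernel(b, b, k_max, submat))
}

# paired bootstrap test of an AUC difference: z from the bootstrap sd
# of the difference, two-sided normal p
oracle_bootstrap_delong <- function(scores_a, scores_b, labels,
                                    n_boot = 10000, seed = 1) {
  set.seed(seed)
  d0 <- oracle_auc(scores_a, labels) - oracle_auc(scores_b, labels)
  n <- length(labels)
  diffs <- replicate(n_boot, {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(labels[idx])) < 2) return(NA_real_)
    oracle_auc(scores_a[idx], labels[idx]) -
      oracle_auc(scores_b[idx], labels[idx])
  })
  z <- d0 / stats::sd(diffs, na.rm = TRUE)
  2 * stats::pnorm(-abs(z))
}

random_peptide <- function(L) {
  paste(sample(neopredict::AA_ALPHABET, L, replace = TRUE), collapse = "")
}

# small planted-signal cohort shared by several tests
small_cohort <- function(seed = 1, n_patients = 30,
                         per_patient = c(30, 36)) {
  generateCohort(syntheticConfig(
    n_patients = n_patients, peptides_per_patient = per_patient,
    seed = seed))
}

# patient-stratified label permutation, applied consistently to the
# record table (drives partitioning) and the feature table (drives CV)
permute_cohort_labels <- function(records, tab, seed) {
  set.seed(seed)
  for (p in unique(records$patient_id)) {
    i <- which(records$patient_id == p)
    records$label[i] <- sample(records$label[i])
  }
  labels <- records$label[match(peptideInfo(tab)$peptide_id,
                                records$peptide_id)]
  tab2 <- new("FeatureTable", info = peptideInfo(tab),
              features = featureMatrix(tab), labels = as.integer(labels),
              featureMeta = tab@featureMeta)
  list(records = records, table = tab2)
}
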