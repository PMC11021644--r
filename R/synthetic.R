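## Synthetic multi-patient neoepitope screen with planted signal. The
## generator emulates the structure of a barcode-multimer screen: many
## patients, 100-400 pre-filtered candidates each (eluted-ligand rank
## < 2 enforced), ~2.7% immunogenic, sequence-linked immunogenicity
## signal (core hydrophobicity and hydrophobic/aromatic content),
## mutation-quality and patient-level TME covariates, RNA read counts
## and survival times tied to the true immunogenic burden.

## approximate human proteome residue frequencies
HUMAN_AA_FREQ <- c(
  A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037, G = 0.066,
  H = 0.026, I = 0.043, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
  P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.053, V = 0.060,
  W = 0.012, Y = 0.027)

#' Configuration of the synthetic screen generator
#'
#' Defaults describe the emulated study conditions: 30 patients with
#' 100-400 candidates each, a 2.7% positive rate, peptide lengths
#' 8:9:10:11 in proportions 10:60:20:10 (the class-I ligand length
#' bias), and logit coefficients planting signal in core
#' hydrophobicity, hydrophobic/aromatic content, the eluted-ligand
#' rank, cellular prevalence and the patient's cytolytic activity.
#'
#' @param n_patients number of patients.
#' @param peptides_per_patient length-2 integer range.
#' @param prevalence target positive rate.
#' @param weights named logit coefficients (HydroCore, PropHydroAro,
#'   logRankEL, CelPrev, CYT) applied to cohort-standardized values.
#' @param motif_share_rate fraction of immunogenic peptides whose
#'   sequence is duplicated into another patient (exercises motif
#'   clustering).
#' @param frameshift_rate fraction of records without a wild-type
#'   sequence.
#' @param residue_freqs "uniform" or "human".
#' @param lengths,length_probs candidate peptide lengths and their
#'   sampling probabilities.
#' @param seed integer RNG seed.
#' @return named list of class parameters.
#' @export
syntheticConfig <- function(n_patients = 30L,
                            peptides_per_patient = c(100L, 400L),
                            prevalence = 0.027,
                            weights = c(HydroCore = 1.0, PropHydroAro = 0.7,
                                        logRankEL = -0.7, CelPrev = 0.4,
                                        CYT = 0.8),
                            motif_share_rate = 0.10,
                            frameshift_rate = 0.10,
                            residue_freqs = c("uniform", "human"),
                            lengths = 8:11,
                            length_probs = c(0.1, 0.6, 0.2, 0.1),
                            seed = 1L) {
  residue_freqs <- match.arg(residue_freqs)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (any(!is.finite(weights))) stop("weights must be finite")
  list(n_patients = as.integer(n_patients),
       peptides_per_patient = as.integer(peptides_per_patient),
       prevalence = prevalence, weights = weights,
       motif_share_rate = motif_share_rate,
       frameshift_rate = frameshift_rate,
       residue_freqs = residue_freqs, lengths = as.integer(lengths),
       length_probs = length_probs, seed = as.integer(seed))
}

.randomPeptide <- function(L, probs) {
  paste(sample(AA_ALPHABET, L, replace = TRUE, prob = probs), collapse = "")
}

.centralCore <- function(seq) {
  L <- nchar(seq)
  if (L >= 9L) {
    start <- (L - 9L) %/% 2L
    list(core9 = substr(seq, start + 1L, start + 9L), core_start = start)
  } else {
    ## 8-mer: central insertion, marked with the wildcard X
    list(core9 = paste0(substr(seq, 1L, 4L), "X", substr(seq, 5L, 8L)),
         core_start = 0L)
  }
}

#' Generate a synthetic neoepitope screen
#'
#' Draws the full input set of the pipeline: peptide records with
#' external prediction columns, per-patient expression profiles,
#' per-mutation RNA read counts, a survival table, and the ground-truth
#' generator parameters. Labels follow a logistic model on
#' cohort-standardized planted covariates with the intercept solved so
#' the expected positive rate equals the configured prevalence.
#' Survival times are exponential with rate decreasing in the patient's
#' true immunogenic count. Fully deterministic given the seed.
#'
#' @param config from \code{\link{syntheticConfig}}.
#' @return list with records, profiles, rna_counts, survival, truth.
#' @export
generateCohort <- function(config = syntheticConfig()) {
  set.seed(config$seed)
  np <- config$n_patients
  patients <- sprintf("P%02d", seq_len(np))
  freqs <- if (config$residue_freqs == "human") HUMAN_AA_FREQ[AA_ALPHABET]
           else rep(1 / 20, 20)

  ## patient-level TME scalar drives both the expression profile and,
  ## through the CYT weight, the patient's positive rate
  tme <- stats::rnorm(np)
  profiles <- stats::setNames(vector("list", np), patients)
  for (i in seq_len(np)) {
    genes <- c(GZMA = exp(log(20) + 0.9 * tme[i] + stats::rnorm(1, 0, 0.15)),
               PRF1 = exp(log(15) + 0.9 * tme[i] + stats::rnorm(1, 0, 0.15)),
               stats::setNames(
                 exp(log(50) + stats::rnorm(3, 0, 0.4)), DEFAULT_HLA_GENES),
               stats::setNames(
                 exp(log(8) + 0.5 * tme[i] +
                       stats::rnorm(length(unlist(DEFAULT_MARKER_SETS)), 0, 0.3)),
                 unlist(DEFAULT_MARKER_SETS)))
    profiles[[i]] <- genes
  }

  lo <- config$peptides_per_patient[1]
  hi <- config$peptides_per_patient[2]
  n_per <- lo + sample.int(hi - lo + 1L, np, replace = TRUE) - 1L
  n <- sum(n_per)
  patient_id <- rep(patients, n_per)

  L <- sample(config$lengths, n, replace = TRUE, prob = config$length_probs)
  mut_seq <- vapply(L, .randomPeptide, character(1), probs = freqs)
  cores <- lapply(mut_seq, .centralCore)
  core9 <- vapply(cores, `[[`, character(1), "core9")
  core_start <- vapply(cores, `[[`, integer(1), "core_start")

  ## wild type: single substitution (missense) or absent (frameshift)
  frameshift <- stats::runif(n) < config$frameshift_rate
  wt_seq <- vapply(seq_len(n), function(i) {
    if (frameshift[i]) return(NA_character_)
    chars <- strsplit(mut_seq[i], "")[[1]]
    pos <- sample(L[i], 1)
    chars[pos] <- sample(setdiff(AA_ALPHABET, chars[pos]), 1)
    paste(chars, collapse = "")
  }, character(1))

  ## external predictions; the screen pre-filter keeps RankEL below 2,
  ## with the two-peak strong/weak binder structure
  strong <- stats::runif(n) < 0.6
  rank_el_mut <- ifelse(strong,
                        10^stats::runif(n, log10(0.01), log10(0.5)),
                        stats::runif(n, 0.5, 2))
  rank_el_wt <- ifelse(frameshift, NA_real_,
                       pmin(pmax(rank_el_mut *
                                   exp(stats::rnorm(n, 0.3, 0.9)),
                                 0.01), 100))
  rank_ba_mut <- pmin(pmax(rank_el_mut * exp(stats::rnorm(n, 0, 0.5)),
                           0.005), 100)
  stability <- exp(stats::rnorm(n, log(2), 0.7))
  netmhc_exp <- -log10(rank_el_mut) + stats::rnorm(n, 0, 0.3)
  prime <- stats::rbeta(n, 2, 5)
  foreignness <- stats::rbeta(n, 0.3, 3)
  expression <- exp(stats::rnorm(n, log(10), 1.2))
  var_al_frac <- stats::rbeta(n, 5, 8)
  cel_prev <- stats::rbeta(n, 6, 2)
  prio_score <- stats::plogis(-log(rank_el_mut) / 2 +
                                log1p(expression) / 4 +
                                stats::rnorm(n, 0, 0.5))

  ## planted logistic immunogenicity model on standardized covariates
  hydro_core <- vapply(core9, function(cc)
    hydrophobicityMean(nonAnchorSubsequence(cc)), numeric(1))
  prop_ha <- vapply(mut_seq, classProportion, numeric(1),
                    residues = RESIDUE_CLASSES$hydro_aro)
  z <- function(v) (v - mean(v)) / stats::sd(v)
  w <- config$weights
  eta <- w[["HydroCore"]] * z(hydro_core) +
    w[["PropHydroAro"]] * z(prop_ha) +
    w[["logRankEL"]] * z(log(rank_el_mut)) +
    w[["CelPrev"]] * z(cel_prev) +
    w[["CYT"]] * rep(tme, n_per)
  b0 <- if (all(w == 0)) stats::qlogis(config$prevalence)
  else stats::uniroot(function(b) mean(stats::plogis(b + eta)) -
                        config$prevalence, c(-20, 10))$root
  p <- stats::plogis(b0 + eta)
  label <- NULL
  for (round in 1:100) {
    cand <- stats::rbinom(n, 1, p)
    if (sum(cand) >= 2 && sum(cand) < n) { label <- cand; break }
  }
  if (is.null(label))
    stop("could not realize the target prevalence in 100 rejection rounds")

  ## duplicate a fraction of immunogenic sequences across patients so
  ## the motif clustering has work to do
  pos_idx <- which(label == 1)
  n_share <- floor(config$motif_share_rate * length(pos_idx))
  if (n_share >= 1 && length(pos_idx) >= 2) {
    src <- sample(pos_idx, n_share)
    for (i in src) {
      other <- pos_idx[patient_id[pos_idx] != patient_id[i]]
      if (!length(other)) next
      j <- if (length(other) == 1L) other else sample(other, 1)
      mut_seq[j] <- mut_seq[i]; wt_seq[j] <- wt_seq[i]
      core9[j] <- core9[i]; core_start[j] <- core_start[i]
      L[j] <- L[i]; frameshift[j] <- frameshift[i]
    }
  }

  records <- data.frame(
    peptide_id = sprintf("pep%05d", seq_len(n)),
    patient_id = patient_id,
    mut_seq = mut_seq, wt_seq = wt_seq,
    hla = sample(c("HLA-A02:01", "HLA-A01:01", "HLA-B07:02", "HLA-B15:01",
                   "HLA-C06:02"), n, replace = TRUE),
    core9 = core9, core_start = core_start,
    label = label,
    rank_el_mut = rank_el_mut, rank_el_wt = rank_el_wt,
    rank_ba_mut = rank_ba_mut, stability = stability,
    netmhc_exp = netmhc_exp, prime = prime, foreignness = foreignness,
    expression = expression, var_al_frac = var_al_frac,
    cel_prev = cel_prev, prio_score = prio_score,
    stringsAsFactors = FALSE)

  coverage <- stats::rnbinom(n, size = 2, mu = 60)
  rna_counts <- data.frame(
    peptide_id = records$peptide_id,
    n_variant_reads = stats::rbinom(n, coverage, var_al_frac),
    n_coverage_reads = coverage)

  true_pos <- tapply(label, patient_id, sum)[patients]
  rate <- 0.002 * exp(-0.35 * as.numeric(scale(log1p(true_pos))))
  surv <- data.frame(
    patient_id = patients,
    time = stats::rexp(np, rate),
    event = stats::rbinom(np, 1, 0.7))

  list(records = records, profiles = profiles, rna_counts = rna_counts,
       survival = surv,
       truth = list(weights = w, intercept = b0, tme = stats::setNames(tme, patients),
                    prevalence_target = config$prevalence,
                    planted = c("HydroCore", "PropHydroAro", "RankEL"),
                    true_positive_count = true_pos))
}

#' Run the full pipeline on a synthetic cohort and report recovery
#'
#' Assembles the feature table, builds leakage-aware partitions, runs
#' cross-validation and compares the model against the RankEL-only
#' baseline: global AUC/AUC01, mean per-patient AUC01, per-patient
#' top-k capture, and the importance ranks of the planted features.
#'
#' @param cohort from \code{\link{generateCohort}}.
#' @param config ensemble configuration (default the fast test
#'   profile).
#' @param feature_set one of "standard", "simple", "tme".
#' @param n_folds,motif_k partitioning parameters.
#' @param top_k list depth for the per-patient capture (default 20).
#' @return list of metrics (see Details in the vignette).
#' @export
recoverParameters <- function(cohort, config = ensembleConfig("test"),
                              feature_set = "standard", n_folds = 5L,
                              motif_k = 6L, top_k = 20L) {
  tab <- assembleFeatureTable(cohort$records, cohort$profiles,
                              cohort$rna_counts)
  parts <- assignPartitions(cohort$records, n_folds, motif_k)
  cv <- crossValidate(tab, parts, config,
                      features = intersect(featureSet(feature_set),
                                           colnames(featureMatrix(tab))))
  sc <- cvScores(cv)
  roc_model <- rocCurve(sc$score, sc$label)

  ## RankEL baseline on the same peptides (lower rank = more positive)
  rank_el <- cohort$records$rank_el_mut[
    match(sc$peptide_id, cohort$records$peptide_id)]
  roc_rank <- rocCurve(rank_el, sc$label, higher_is_positive = FALSE)

  per_patient_auc01 <- function(scores, labels, pats, higher = TRUE) {
    vals <- vapply(unique(pats), function(p) {
      i <- pats == p
      if (length(unique(labels[i])) < 2L) return(NA_real_)
      rocCurve(scores[i], labels[i], higher_is_positive = higher)$pauc01
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }

  imp <- featureImportance(cv)
  list(
    auc = roc_model$auc, auc01 = roc_model$pauc01,
    rankel_auc = roc_rank$auc, rankel_auc01 = roc_rank$pauc01,
    per_patient_auc01 = per_patient_auc01(sc$score, sc$label, sc$patient_id),
    rankel_per_patient_auc01 = per_patient_auc01(rank_el, sc$label,
                                                 sc$patient_id, FALSE),
    topk_model = mean(perPatientTopK(sc$score, sc$label, sc$patient_id,
                                     top_k, sc$peptide_id), na.rm = TRUE),
    topk_rankel = mean(perPatientTopK(rank_el, sc$label, sc$patient_id,
                                      top_k, sc$peptide_id,
                                      higher_is_positive = FALSE),
                       na.rm = TRUE),
    importance = imp,
    planted_rank = match(c("HydroCore", "PropHydroAro"), imp$feature),
    cv = cv)
}
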