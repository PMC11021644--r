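## End-to-end wiring: simulate -> featurize -> partition -> cv ->
## evaluate -> survival stratification, with all artifacts written to
## disk and a manifest recording configuration and versions. The
## command-line entry point in inst/scripts/neopredict is a thin layer
## over these exported functions.

#' Run the full pipeline on a synthetic cohort
#'
#' Generates (or loads) a cohort, computes features, builds
#' leakage-aware partitions, cross-validates the balanced ensemble,
#' evaluates against the RankEL baseline, derives the
#' sensitivity/specificity-intersection cutoff, and stratifies patient
#' survival by predicted neoepitope load. All outputs are TSV/JSON
#' files under \code{out_dir}.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving simulation and training.
#' @param profile ensemble profile, "test" (default) or "full".
#' @param feature_set model feature set name.
#' @param synthetic_config optional \code{\link{syntheticConfig}}
#'   overriding the default cohort.
#' @param n_folds,motif_k partitioning parameters.
#' @return invisibly, a list with the metrics and survival results.
#' @export
runPipeline <- function(out_dir, seed = 1L, profile = "test",
                        feature_set = "standard",
                        synthetic_config = NULL, n_folds = 5L,
                        motif_k = 6L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(synthetic_config)) synthetic_config <- syntheticConfig(seed = seed)
  cohort <- generateCohort(synthetic_config)

  ## persist the simulated inputs
  utils::write.table(cohort$records, file.path(out_dir, "records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expr <- do.call(cbind, cohort$profiles)
  utils::write.table(
    data.frame(gene = rownames(expr), expr, check.names = FALSE),
    file.path(out_dir, "expression.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$rna_counts, file.path(out_dir, "rna_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$survival, file.path(out_dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tab <- assembleFeatureTable(cohort$records, cohort$profiles,
                              cohort$rna_counts)
  writeFeatureTable(tab, file.path(out_dir, "features.tsv"))
  parts <- assignPartitions(cohort$records, n_folds, motif_k)
  writePartitions(parts, file.path(out_dir, "partitions.tsv"))

  config <- ensembleConfig(profile, seed = seed)
  cv <- crossValidate(tab, parts, config,
                      features = intersect(featureSet(feature_set),
                                           colnames(featureMatrix(tab))))
  sc <- cvScores(cv)
  utils::write.table(sc, file.path(out_dir, "cv_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  roc <- rocCurve(sc$score, sc$label)
  cutoff <- sensSpecIntersection(sc$score, sc$label)
  cm <- confusionAt(sc$score, sc$label, cutoff)
  metrics <- list(
    n_peptides = nrow(sc), n_positive = sum(sc$label),
    auc = roc$auc, auc01 = roc$pauc01,
    average_precision = prMetrics(sc$score, sc$label)$average_precision,
    cutoff = cutoff,
    confusion = list(tp = cm@tp, fp = cm@fp, fn = cm@fn, tn = cm@tn),
    mcc = mcc(cm), accuracy = accuracy(cm),
    top20_capture = mean(perPatientTopK(sc$score, sc$label, sc$patient_id,
                                        20, sc$peptide_id), na.rm = TRUE))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(roc$curve, file.path(out_dir, "roc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  surv <- survivalByLoad(sc$score, sc$patient_id, cutoff, cohort$survival)
  jsonlite::write_json(
    list(logrank = surv$logrank,
         cox = surv$cox[c("hr", "beta", "se", "p")],
         groups = as.list(table(surv$groups))),
    file.path(out_dir, "survival_stats.json"), auto_unbox = TRUE,
    digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("neopredict")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, profile = profile, feature_set = feature_set,
    n_folds = n_folds, motif_k = motif_k,
    ensemble = config, synthetic = synthetic_config[
      setdiff(names(synthetic_config), "weights")],
    planted_weights = as.list(synthetic_config$weights))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(metrics = metrics, survival = surv, cv = cv,
                 cohort = cohort))
}
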