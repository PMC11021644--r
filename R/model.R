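## The class-balanced random-forest subsampling ensemble and its
## cross-validated training loop. Forests are fitted with ranger; the
## balancing scheme (all positives + repeated 500-negative draws),
## per-fold feature selection, imputation and deduplication are wired
## here.

#' Ensemble hyperparameter configuration
#'
#' Defaults are the full-fidelity settings (2,000 trees per forest, 50
#' negative subsamples of 500). The "test" profile shrinks the ensemble
#' to 200 trees x 10 subsamples for fast exploratory runs; all other
#' settings are shared.
#'
#' @param profile "full" or "test".
#' @param max_depth maximum tree depth.
#' @param n_estimators trees per forest.
#' @param min_samples_leaf minimum terminal-node size.
#' @param n_subsamples number of balanced negative draws (= forests).
#' @param n_negatives_per_subsample negatives per draw.
#' @param seed integer RNG seed governing draws and forests.
#' @return named list.
#' @export
ensembleConfig <- function(profile = c("full", "test"), max_depth = 6L,
                           n_estimators = NULL, min_samples_leaf = 6L,
                           n_subsamples = NULL,
                           n_negatives_per_subsample = 500L, seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(n_estimators))
    n_estimators <- if (profile == "full") 2000L else 200L
  if (is.null(n_subsamples))
    n_subsamples <- if (profile == "full") 50L else 10L
  cfg <- list(max_depth = as.integer(max_depth),
              n_estimators = as.integer(n_estimators),
              min_samples_leaf = as.integer(min_samples_leaf),
              n_subsamples = as.integer(n_subsamples),
              n_negatives_per_subsample = as.integer(n_negatives_per_subsample),
              seed = as.integer(seed))
  if (any(unlist(cfg) < 1L)) stop("all configuration values must be positive")
  cfg
}

#' Train the balanced subsampling ensemble
#'
#' Fits \code{n_subsamples} probability forests. Every forest sees all
#' training positives plus an independent draw (without replacement) of
#' \code{n_negatives_per_subsample} negatives; when fewer negatives are
#' available, each draw uses all of them (with a warning). The table
#' must already be imputed (no missing entries in the used features).
#'
#' @param table FeatureTable, imputed.
#' @param config from \code{\link{ensembleConfig}}.
#' @param features feature columns to use (default all).
#' @param fold training-fold id stored for bookkeeping.
#' @param impute_means training means to store for scoring new data.
#' @return a \code{\link{TrainedEnsemble}}.
#' @export
trainBalancedEnsemble <- function(table, config = ensembleConfig(),
                                  features = NULL, fold = NA_integer_,
                                  impute_means = NULL) {
  m <- featureMatrix(table)
  labels <- peptideLabels(table)
  if (is.null(features)) features <- colnames(m)
  m <- m[, features, drop = FALSE]
  if (anyNA(m)) stop("training table contains missing values; impute first")
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (!length(pos)) stop("no positive training examples")
  n_draw <- config$n_negatives_per_subsample
  if (length(neg) < n_draw) {
    warning("only ", length(neg), " negatives available; each draw uses ",
            "all of them instead of ", n_draw)
    n_draw <- length(neg)
  }
  if (is.null(impute_means)) impute_means <- colMeans(m)

  forests <- vector("list", config$n_subsamples)
  for (s in seq_len(config$n_subsamples)) {
    ## independent RNG stream per subsample index, reproducible from seed
    set.seed(config$seed * 1000L + s)
    draw <- if (n_draw == length(neg)) neg else sample(neg, n_draw)
    idx <- c(pos, draw)
    df <- as.data.frame(m[idx, , drop = FALSE])
    forests[[s]] <- ranger::ranger(
      x = df, y = factor(labels[idx], levels = c(0L, 1L)),
      num.trees = config$n_estimators,
      max.depth = config$max_depth,
      min.node.size = config$min_samples_leaf,
      probability = TRUE, importance = "impurity",
      seed = config$seed * 1000L + s, num.threads = 1L)
  }
  new("TrainedEnsemble", forests = forests, features = features,
      imputeMeans = impute_means[features], config = config,
      fold = as.integer(fold))
}

#' Score peptides with a trained ensemble
#'
#' Missing entries are filled with the ensemble's stored training
#' means; the score is the arithmetic mean of the forests'
#' positive-class probabilities.
#'
#' @param object a \code{\link{TrainedEnsemble}}.
#' @param table FeatureTable (or numeric matrix) to score.
#' @param ... unused.
#' @return numeric score vector in [0, 1].
#' @export
setMethod("predict", "TrainedEnsemble", function(object, table, ...) {
  m <- if (is(table, "FeatureTable")) featureMatrix(table) else table
  miss <- setdiff(object@features, colnames(m))
  if (length(miss))
    stop("table lacks feature column(s): ", paste(miss, collapse = ", "))
  m <- m[, object@features, drop = FALSE]
  for (f in object@features) {
    na <- is.na(m[, f])
    if (any(na)) m[na, f] <- object@imputeMeans[[f]]
  }
  df <- as.data.frame(m)
  preds <- vapply(object@forests, function(fr)
    stats::predict(fr, data = df, num.threads = 1L)$predictions[, "1"],
    numeric(nrow(df)))
  if (nrow(df) == 1L) mean(preds) else rowMeans(preds)
})

#' Leakage-aware cross-validation
#'
#' For each fold: restrict to training rows, deduplicate against the
#' test fold by mutant sequence, run the Spearman correlation filter
#' and mean imputation on the training rows only, train the balanced
#' ensemble, and score the held-out fold (imputed with training means).
#' Every peptide receives exactly one out-of-fold score.
#'
#' @param table FeatureTable.
#' @param partitions a \code{\link{PartitionAssignment}} covering the
#'   table's peptides.
#' @param config from \code{\link{ensembleConfig}}.
#' @param features candidate feature columns (default
#'   \code{featureSet("standard")} intersected with the table).
#' @param corr_threshold Spearman threshold for the feature filter.
#' @param filter_measure univariate criterion for the filter.
#' @return a \code{\link{CVResult}}.
#' @export
crossValidate <- function(table, partitions, config = ensembleConfig(),
                          features = NULL, corr_threshold = 0.7,
                          filter_measure = "auc01") {
  info <- peptideInfo(table)
  labels <- peptideLabels(table)
  fold <- foldOf(partitions)[info$peptide_id]
  if (anyNA(fold)) stop("partition assignment does not cover every peptide")
  if (is.null(features))
    features <- intersect(featureSet("standard"),
                          colnames(featureMatrix(table)))
  ## a column with no observed value at all cannot be used or imputed
  observed <- colSums(!is.na(featureMatrix(table)[, features, drop = FALSE]))
  if (any(observed == 0)) {
    message("dropping feature(s) with no observed values: ",
            paste(features[observed == 0], collapse = ", "))
    features <- features[observed > 0]
  }
  seqs <- if ("mut_seq" %in% names(info))
    stats::setNames(info$mut_seq, info$peptide_id) else NULL

  out <- vector("list", partitions@nFolds)
  fold_feats <- vector("list", partitions@nFolds)
  fold_imp <- vector("list", partitions@nFolds)
  for (f in sort(unique(fold))) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    if (!length(test_idx) || !length(train_idx))
      stop("fold ", f, " leaves an empty train or test set")
    train_ids <- info$peptide_id[train_idx]
    if (!is.null(seqs))
      train_ids <- dedupTrain(train_ids, info$peptide_id[test_idx], seqs)
    train_tab <- table[match(train_ids, info$peptide_id)]
    test_tab <- table[test_idx]

    kept <- correlationFilter(train_tab, threshold = corr_threshold,
                              measure = filter_measure, features = features)
    imp <- imputeMean(train_tab, features = kept)
    test_imp <- imputeMean(train_tab, test_tab, features = kept)$table
    fit <- trainBalancedEnsemble(imp$table, config, features = kept,
                                 fold = f, impute_means = imp$means)
    scores <- predict(fit, test_imp)

    ## per-fold importance: normalize each forest's impurity importances
    ## to sum 1, then average across forests
    imps <- vapply(fit@forests, function(fr) {
      v <- fr$variable.importance
      v / sum(v)
    }, numeric(length(kept)))
    fold_imp[[f]] <- rowMeans(imps)
    fold_feats[[f]] <- kept
    out[[f]] <- data.frame(
      peptide_id = info$peptide_id[test_idx],
      patient_id = info$patient_id[test_idx],
      fold = f, score = scores, label = labels[test_idx],
      stringsAsFactors = FALSE)
  }
  new("CVResult", scores = do.call(rbind, out), foldFeatures = fold_feats,
      importance = fold_imp, config = config)
}

#' Mean feature importance across folds
#'
#' Impurity importances are normalized within each forest, averaged over
#' the forests of a fold, then averaged over folds; a feature that was
#' deselected in a fold contributes 0 for that fold.
#'
#' @param cv_result a \code{\link{CVResult}}.
#' @return data.frame (feature, importance), sorted decreasing.
#' @export
featureImportance <- function(cv_result) {
  all_feats <- sort(unique(unlist(cv_result@foldFeatures)))
  per_fold <- vapply(cv_result@importance, function(v) {
    out <- stats::setNames(numeric(length(all_feats)), all_feats)
    out[names(v)] <- v
    out
  }, numeric(length(all_feats)))
  imp <- rowMeans(per_fold)
  df <- data.frame(feature = names(imp), importance = unname(imp),
                   stringsAsFactors = FALSE)
  df[order(-df$importance, df$feature), , drop = FALSE]
}
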