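#' @import methods
NULL

#' FeatureTable: assembled per-peptide feature matrix
#'
#' Container for the assembled modeling dataset: one row per neopeptide
#' candidate, one column per numeric feature, plus the binary
#' immunogenicity label and peptide/patient identifiers. Missing entries
#' (\code{NA}) are permitted until \code{\link{imputeMean}} is applied.
#'
#' @slot info data.frame with columns \code{peptide_id}, \code{patient_id}
#'   (and optionally \code{mut_seq}) aligned with the matrix rows.
#' @slot features numeric matrix, rows = peptides, named columns = features.
#' @slot labels integer vector of 0/1 immunogenicity labels.
#' @slot featureMeta data.frame with columns \code{feature}, \code{category}
#'   (one of mutation-quality, pMHC, physicochemical, TME, external).
#' @export
setClass("FeatureTable",
  representation(info = "data.frame", features = "matrix",
                 labels = "integer", featureMeta = "data.frame"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@features)
    if (nrow(object@info) != n)
      msg <- c(msg, "info and feature matrix row counts differ")
    if (length(object@labels) != n)
      msg <- c(msg, "labels length differs from row count")
    if (!all(object@labels %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0/1")
    if (anyDuplicated(object@info$peptide_id))
      msg <- c(msg, paste("duplicate peptide_id:",
        paste(unique(object@info$peptide_id[duplicated(object@info$peptide_id)]),
              collapse = ", ")))
    if (is.null(colnames(object@features)))
      msg <- c(msg, "feature matrix must have column names")
    if (length(msg)) msg else TRUE
  })

#' PartitionAssignment: leakage-aware fold map
#'
#' Maps every peptide to one of K cross-validation folds such that all
#' peptides of a patient share a fold and no two motif-sharing immunogenic
#' peptides lie in different folds.
#'
#' @slot fold named integer vector (names = peptide_id, values in 1..K).
#' @slot nFolds integer fold count K.
#' @slot components named integer vector mapping patient_id to the
#'   connected component that fixed its fold.
#' @export
setClass("PartitionAssignment",
  representation(fold = "integer", nFolds = "integer", components = "integer"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@fold))) msg <- c(msg, "fold vector must be named")
    if (any(object@fold < 1L | object@fold > object@nFolds))
      msg <- c(msg, "fold indices out of range")
    if (length(msg)) msg else TRUE
  })

#' TrainedEnsemble: balanced random-forest subsampling ensemble
#'
#' The fitted model of one training set: \code{n_subsamples} random
#' forests, each trained on all positives plus an independent draw of
#' \code{n_negatives_per_subsample} negatives, together with the feature
#' list retained by the correlation filter and the training-set
#' imputation means needed to score new data.
#'
#' @slot forests list of fitted ranger forests.
#' @slot features character vector of feature names used.
#' @slot imputeMeans named numeric vector of training-set feature means.
#' @slot config list of hyperparameters (see \code{\link{ensembleConfig}}).
#' @slot fold integer, the training fold id (NA when trained on all data).
#' @export
setClass("TrainedEnsemble",
  representation(forests = "list", features = "character",
                 imputeMeans = "numeric", config = "list", fold = "integer"))

#' CVResult: out-of-fold cross-validation predictions
#'
#' @slot scores data.frame with columns peptide_id, patient_id, fold,
#'   score, label: every peptide scored exactly once, by the ensemble of
#'   the fold that excluded it.
#' @slot foldFeatures list (per fold) of retained feature names.
#' @slot importance list (per fold) of named mean impurity importances.
#' @slot config list of hyperparameters used.
#' @export
setClass("CVResult",
  representation(scores = "data.frame", foldFeatures = "list",
                 importance = "list", config = "list"),
  validity = function(object) {
    need <- c("peptide_id", "patient_id", "fold", "score", "label")
    if (!all(need %in% names(object@scores)))
      return(paste("scores must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(object@scores$peptide_id))
      return("a peptide was scored more than once")
    TRUE
  })

## ---- generics -------------------------------------------------------------

#' @rdname FeatureTable-class
#' @param x a FeatureTable
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname FeatureTable-class
#' @export
setGeneric("peptideInfo", function(x) standardGeneric("peptideInfo"))
#' @rdname FeatureTable-class
#' @export
setGeneric("peptideLabels", function(x) standardGeneric("peptideLabels"))
#' @rdname PartitionAssignment-class
#' @param x a PartitionAssignment
#' @export
setGeneric("foldOf", function(x) standardGeneric("foldOf"))
#' @rdname CVResult-class
#' @param x a CVResult
#' @export
setGeneric("cvScores", function(x) standardGeneric("cvScores"))

#' @rdname FeatureTable-class
setMethod("featureMatrix", "FeatureTable", function(x) x@features)
#' @rdname FeatureTable-class
setMethod("peptideInfo", "FeatureTable", function(x) x@info)
#' @rdname FeatureTable-class
setMethod("peptideLabels", "FeatureTable", function(x) x@labels)
#' @rdname PartitionAssignment-class
setMethod("foldOf", "PartitionAssignment", function(x) x@fold)
#' @rdname CVResult-class
setMethod("cvScores", "CVResult", function(x) x@scores)

#' @rdname FeatureTable-class
#' @aliases dim,FeatureTable-method
setMethod("dim", "FeatureTable", function(x) dim(x@features))

#' Subset a FeatureTable by row
#' @param x FeatureTable
#' @param i row index
#' @param j unused
#' @param ... unused
#' @param drop unused
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  new("FeatureTable",
      info = x@info[i, , drop = FALSE],
      features = x@features[i, , drop = FALSE],
      labels = x@labels[i],
      featureMeta = x@featureMeta)
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d peptides x %d features (%d patients)\n",
              nrow(object@features), ncol(object@features),
              length(unique(object@info$patient_id))))
  cat(sprintf("  positives: %d (%.1f%%)\n", sum(object@labels),
              100 * mean(object@labels)))
  miss <- colMeans(is.na(object@features))
  if (any(miss > 0))
    cat(sprintf("  columns with missing values: %d (max %.1f%%)\n",
                sum(miss > 0), 100 * max(miss)))
})

setMethod("show", "PartitionAssignment", function(object) {
  cat(sprintf("PartitionAssignment: %d peptides in %d folds\n",
              length(object@fold), object@nFolds))
  print(table(fold = object@fold))
})

setMethod("show", "TrainedEnsemble", function(object) {
  cat(sprintf("TrainedEnsemble: %d forests x %d trees, %d features\n",
              length(object@forests), object@config$n_estimators,
              length(object@features)))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d out-of-fold scores over %d folds\n",
              nrow(object@scores), length(unique(object@scores$fold))))
})
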