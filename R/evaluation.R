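## ROC / PR machinery, the partial AUC at FPR 0.1 used throughout the
## evaluation, the DeLong paired test, the sensitivity/specificity
## intersection cutoff, confusion-matrix statistics and per-patient
## top-k capture. Score orientation is explicit everywhere: predictors
## such as eluted-ligand rank are better when LOW and are handled with
## higher_is_positive = FALSE.

#' ConfusionMatrix: binary classification counts
#'
#' @slot tp,fp,fn,tn non-negative integer counts.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric"),
  validity = function(object) {
    v <- c(object@tp, object@fp, object@fn, object@tn)
    if (any(v < 0)) return("counts must be non-negative")
    if (sum(v) == 0) return("empty confusion matrix")
    TRUE
  })

#' Construct a confusion matrix from counts
#' @param tp,fp,fn,tn counts.
#' @return a ConfusionMatrix.
#' @export
confusionMatrix <- function(tp, fp, fn, tn)
  new("ConfusionMatrix", tp = tp, fp = fp, fn = fn, tn = tn)

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2,
              dimnames = list(predicted = c("pos", "neg"),
                              actual = c("pos", "neg")))
  print(m)
})

.checkBinary <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
}

#' ROC curve with trapezoidal AUC and partial AUC at FPR 0.1
#'
#' Standard threshold sweep with tied scores grouped. The returned
#' curve starts at (0, 0) and ends at (1, 1); \code{auc} is the
#' trapezoidal area and \code{pauc01} the unnormalized partial area on
#' FPR in [0, 0.1] (see \code{\link{partialAuc}}).
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels.
#' @param higher_is_positive orientation flag; set FALSE for predictors
#'   where low values mean positive (e.g. percentile ranks).
#' @return list with \code{curve} (data.frame threshold/fpr/tpr),
#'   \code{auc}, \code{pauc01}.
#' @export
rocCurve <- function(scores, labels, higher_is_positive = TRUE) {
  .checkBinary(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  s <- if (higher_is_positive) scores else -scores
  P <- sum(labels == 1); N <- sum(labels == 0)
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- labels[ord]
  ## group tied scores
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  curve <- data.frame(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp / N),
    tpr = c(0, tp / P))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  res <- list(curve = curve, auc = auc)
  res$pauc01 <- partialAuc(res, fpr_max = 0.1)
  res
}

#' Partial area under the ROC curve
#'
#' Unnormalized area under the ROC curve restricted to
#' FPR in [0, \code{fpr_max}], with linear interpolation of the TPR at
#' \code{fpr_max}. Ranges from 0 to \code{fpr_max} (a perfect
#' classifier at \code{fpr_max} = 0.1 scores 0.1; the chance diagonal
#' scores 0.005). \code{normalized = TRUE} applies the McClish
#' transformation onto [0.5, 1].
#'
#' @param roc result of \code{\link{rocCurve}}.
#' @param fpr_max right edge of the FPR window (default 0.1).
#' @param normalized return the McClish-normalized value instead.
#' @return numeric partial area.
#' @export
partialAuc <- function(roc, fpr_max = 0.1, normalized = FALSE) {
  if (fpr_max <= 0 || fpr_max > 1) stop("fpr_max must be in (0, 1]")
  fpr <- roc$curve$fpr; tpr <- roc$curve$tpr
  keep <- fpr <= fpr_max
  x <- fpr[keep]; y <- tpr[keep]
  if (max(x) < fpr_max) {
    ## interpolate the curve at the window edge
    i <- which(fpr > fpr_max)[1]
    w <- (fpr_max - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
    x <- c(x, fpr_max)
    y <- c(y, tpr[i - 1] + w * (tpr[i] - tpr[i - 1]))
  }
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (!normalized) return(area)
  min_area <- fpr_max^2 / 2
  max_area <- fpr_max
  0.5 * (1 + (area - min_area) / (max_area - min_area))
}

#' Precision-recall curve and average precision
#'
#' Interpolation-free average precision: the sum over threshold groups
#' of precision times the recall increment.
#'
#' @inheritParams rocCurve
#' @return list with \code{curve} (threshold/recall/precision) and
#'   \code{average_precision}.
#' @export
prMetrics <- function(scores, labels, higher_is_positive = TRUE) {
  .checkBinary(labels)
  s <- if (higher_is_positive) scores else -scores
  P <- sum(labels == 1)
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- labels[ord]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  precision <- tp / (tp + fp)
  recall <- tp / P
  ap <- sum(precision * diff(c(0, tp)) / P)
  list(curve = data.frame(threshold = s[last], recall = recall,
                          precision = precision),
       average_precision = ap)
}

## DeLong structural components: for each score vector, the placement
## values of positives among negatives and vice versa
.delongPlacements <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi), auc = mean(psi))
}

#' DeLong test for paired AUC difference
#'
#' Compares the AUCs of two score vectors evaluated on the same labeled
#' instances, using the DeLong covariance estimate of the paired
#' difference and a two-sided normal p-value. Identical score vectors
#' return p = 1 by convention.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared binary labels.
#' @return list with auc_a, auc_b, z, p.
#' @export
delongTest <- function(scores_a, scores_b, labels) {
  .checkBinary(labels)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels))
    stop("scores and labels differ in length")
  if (isTRUE(all.equal(scores_a, scores_b)))
    return(list(auc_a = rocCurve(scores_a, labels)$auc,
                auc_b = rocCurve(scores_b, labels)$auc, z = 0, p = 1))
  pa <- .delongPlacements(scores_a, labels)
  pb <- .delongPlacements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d) > 1e-12)
      stop("zero variance of the AUC difference with unequal AUCs")
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Cutoff where sensitivity and specificity intersect
#'
#' Scans candidate thresholds (the observed score values plus midpoints
#' between consecutive distinct values) and returns the one minimizing
#' |sensitivity - specificity|, with ties broken toward higher
#' specificity. A prediction equal to the threshold counts positive.
#'
#' @inheritParams rocCurve
#' @return numeric threshold (on the original score scale).
#' @export
sensSpecIntersection <- function(scores, labels, higher_is_positive = TRUE) {
  .checkBinary(labels)
  s <- if (higher_is_positive) scores else -scores
  u <- sort(unique(s))
  if (length(u) == 1L) {
    warning("constant scores: returning the single candidate threshold")
    return(if (higher_is_positive) u else -u)
  }
  cand <- sort(unique(c(u, (u[-1] + u[-length(u)]) / 2)))
  P <- sum(labels == 1); N <- sum(labels == 0)
  best_t <- NA_real_; best_gap <- Inf; best_spec <- -Inf
  for (t in cand) {
    pred <- s >= t
    sens <- sum(pred & labels == 1) / P
    spec <- sum(!pred & labels == 0) / N
    gap <- abs(sens - spec)
    if (gap < best_gap - 1e-12 ||
        (gap <= best_gap + 1e-12 && spec > best_spec)) {
      best_gap <- gap; best_t <- t; best_spec <- spec
    }
  }
  if (higher_is_positive) best_t else -best_t
}

#' Confusion matrix at a threshold
#'
#' @inheritParams rocCurve
#' @param threshold decision cutoff; a score equal to the threshold
#'   counts as predicted positive.
#' @return a \code{\link{ConfusionMatrix}}.
#' @export
confusionAt <- function(scores, labels, threshold,
                        higher_is_positive = TRUE) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  pred <- if (higher_is_positive) scores >= threshold
          else scores <= threshold
  confusionMatrix(tp = sum(pred & labels == 1),
                  fp = sum(pred & labels == 0),
                  fn = sum(!pred & labels == 1),
                  tn = sum(!pred & labels == 0))
}

#' Matthews correlation coefficient
#'
#' Standard MCC, with the convention MCC = 0 whenever a marginal total
#' is zero.
#'
#' @param cm a \code{\link{ConfusionMatrix}}.
#' @return numeric in [-1, 1].
#' @export
mcc <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  tp <- as.numeric(cm@tp); fp <- as.numeric(cm@fp)
  fn <- as.numeric(cm@fn); tn <- as.numeric(cm@tn)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Classification accuracy
#' @param cm a \code{\link{ConfusionMatrix}}.
#' @return (tp + tn) / n.
#' @export
accuracy <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  (cm@tp + cm@tn) / (cm@tp + cm@fp + cm@fn + cm@tn)
}

#' Per-patient capture of immunogenic peptides in the top k
#'
#' For each patient, ranks that patient's peptides by score and reports
#' the fraction of the patient's immunogenic peptides found among the
#' top k. Patients without immunogenic peptides yield NA. Rank ties at
#' position k are broken by peptide id.
#'
#' @inheritParams rocCurve
#' @param patient_ids patient of each peptide.
#' @param k list depth (e.g. 20 or 50).
#' @param peptide_ids optional ids for deterministic tie-breaks
#'   (defaults to input order).
#' @return named numeric vector, one fraction per patient.
#' @export
perPatientTopK <- function(scores, labels, patient_ids, k,
                           peptide_ids = NULL, higher_is_positive = TRUE) {
  if (k < 1) stop("k must be >= 1")
  if (is.null(peptide_ids)) peptide_ids <- as.character(seq_along(scores))
  s <- if (higher_is_positive) scores else -scores
  patients <- sort(unique(patient_ids))
  out <- stats::setNames(rep(NA_real_, length(patients)), patients)
  for (p in patients) {
    idx <- which(patient_ids == p)
    npos <- sum(labels[idx] == 1)
    if (npos == 0) next
    ord <- idx[order(-s[idx], peptide_ids[idx])]
    top <- ord[seq_len(min(k, length(ord)))]
    out[[p]] <- sum(labels[top] == 1) / npos
  }
  out
}
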