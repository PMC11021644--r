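## Assembly of the modeling dataset: joining peptide-, mutation- and
## patient-level features, mean imputation, and Spearman-correlation
## feature deselection.

FEATURE_CATEGORIES <- c(
  CelPrev = "mutation-quality", VarAlFrac = "mutation-quality",
  ValMutRNACoef = "mutation-quality", Expression = "mutation-quality",
  PrioScore = "mutation-quality",
  RankEL = "pMHC", RankBA = "pMHC", Stability = "pMHC",
  NetMHCExp = "pMHC", DAI = "pMHC", SelfSim = "pMHC",
  Foreignness = "pMHC", Prime = "pMHC",
  HydroAll = "physicochemical", HydroCore = "physicochemical",
  PropHydroAro = "physicochemical", Aro = "physicochemical",
  PropAro = "physicochemical", PropSmall = "physicochemical",
  PropAcidic = "physicochemical", PropBasic = "physicochemical",
  CysRed = "physicochemical", Inst = "physicochemical",
  pI = "physicochemical", mw = "physicochemical",
  CYT = "TME", MCPmean = "TME", HLAexp = "TME")

.normalizeLabels <- function(label) {
  if (is.numeric(label)) {
    if (!all(label %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(label))
  }
  lab <- tolower(as.character(label))
  out <- ifelse(lab %in% c("immunogenic", "1", "true", "yes"), 1L,
         ifelse(lab %in% c("non-immunogenic", "nonimmunogenic", "0",
                           "false", "no"), 0L, NA_integer_))
  if (anyNA(out)) stop("unrecognized label value(s): ",
                       paste(unique(label[is.na(out)]), collapse = ", "))
  out
}

#' Read a peptide record table
#'
#' Reads the tab-separated input table (one row per neopeptide
#' candidate). Required headers: peptide_id, patient_id, mut_seq,
#' wt_seq, hla, core9, core_start, label; any of the external
#' prediction columns may follow. Empty fields, "NA" and (for
#' expression) "-" are read as missing.
#'
#' @param path TSV file path.
#' @return data.frame of records, labels normalized to 0/1.
#' @export
readPeptideTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  need <- c("peptide_id", "patient_id", "mut_seq", "core9", "core_start",
            "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("input table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if ("expression" %in% names(df) && is.character(df$expression)) {
    df$expression[df$expression == "-"] <- NA
    df$expression <- as.numeric(df$expression)
  }
  df$label <- .normalizeLabels(df$label)
  df
}

#' Read a gene-by-patient expression matrix
#'
#' Accepts either a two-column per-patient table (gene, TPM; returned as
#' a single-profile list) or a gene x patient matrix with a leading
#' `gene` column.
#'
#' @param path TSV file path.
#' @return named list of per-patient named TPM vectors.
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(df)) stop("expression table needs a 'gene' column")
  genes <- df$gene
  vals <- df[setdiff(names(df), "gene")]
  lapply(as.list(vals), function(col) stats::setNames(as.numeric(col), genes))
}

#' Read per-mutation RNA read counts
#' @param path TSV with columns peptide_id, n_variant_reads,
#'   n_coverage_reads.
#' @return data.frame.
#' @export
readRnaCounts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide_id", "n_variant_reads", "n_coverage_reads")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("RNA count table is missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Read a patient survival table
#' @param path TSV with columns patient_id, time, event.
#' @return data.frame.
#' @export
readSurvivalTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survival table is missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Assemble the per-peptide feature matrix
#'
#' Joins sequence-derived features (\code{\link{computePeptideFeatures}}),
#' the RNA validation coefficient, and the patient-level TME covariates
#' into one \code{\link{FeatureTable}}. Records whose patient has no
#' expression profile get missing TME columns; records without RNA
#' counts get a missing ValMutRNACoef. Per-feature missingness rates
#' are recorded in the table's metadata.
#'
#' @param records data.frame of peptide records (see
#'   \code{\link{readPeptideTable}}).
#' @param profiles optional named list (patient_id -> named TPM vector).
#' @param rna_counts optional data.frame (peptide_id, n_variant_reads,
#'   n_coverage_reads).
#' @param marker_sets marker configuration for the population scores.
#' @param ... passed to \code{\link{computePeptideFeatures}}.
#' @return a \code{\link{FeatureTable}}.
#' @export
assembleFeatureTable <- function(records, profiles = NULL, rna_counts = NULL,
                                 marker_sets = DEFAULT_MARKER_SETS, ...) {
  if (!nrow(records)) stop("no peptide records supplied")
  dup <- unique(records$peptide_id[duplicated(records$peptide_id)])
  if (length(dup))
    stop("duplicate peptide_id: ", paste(dup, collapse = ", "))

  feats <- computePeptideFeatures(records, ...)
  kept <- records[!records$peptide_id %in% attr(feats, "skipped"), ,
                  drop = FALSE]

  if (!is.null(rna_counts)) {
    idx <- match(kept$peptide_id, rna_counts$peptide_id)
    feats$ValMutRNACoef <- ifelse(is.na(idx), NA_real_,
      valMutRnaCoef(rna_counts$n_variant_reads[idx],
                    rna_counts$n_coverage_reads[idx]))
  } else feats$ValMutRNACoef <- NA_real_

  tme <- c("CYT", "MCPmean", "HLAexp")
  for (col in tme) feats[[col]] <- NA_real_
  if (!is.null(profiles)) {
    for (pid in unique(kept$patient_id)) {
      if (is.null(profiles[[pid]])) next
      tf <- tmeFeatures(profiles[[pid]], marker_sets)
      rows <- kept$patient_id == pid
      feats$CYT[rows] <- tf$cyt
      feats$MCPmean[rows] <- tf$mcp_mean
      feats$HLAexp[rows] <- tf$hla_exp
    }
  }

  m <- as.matrix(feats)
  mode(m) <- "numeric"
  meta <- data.frame(
    feature = colnames(m),
    category = unname(FEATURE_CATEGORIES[colnames(m)]),
    missing_rate = colMeans(is.na(m)),
    row.names = NULL, stringsAsFactors = FALSE)
  meta$category[is.na(meta$category)] <- "external"

  info_cols <- intersect(c("peptide_id", "patient_id", "mut_seq", "hla"),
                         names(kept))
  new("FeatureTable",
      info = kept[info_cols],
      features = m,
      labels = .normalizeLabels(kept$label),
      featureMeta = meta)
}

#' Mean imputation with training-set means
#'
#' Computes per-feature means on the training table only and fills them
#' into the missing entries of the apply table. Idempotent on complete
#' tables; observed values are never altered.
#'
#' @param train_table FeatureTable providing the means.
#' @param apply_table FeatureTable to fill (defaults to the training
#'   table itself).
#' @param features columns to impute (default all shared columns).
#' @return list with elements \code{table} (imputed apply_table) and
#'   \code{means} (named numeric).
#' @export
imputeMean <- function(train_table, apply_table = train_table,
                       features = NULL) {
  tm <- featureMatrix(train_table)
  am <- featureMatrix(apply_table)
  if (is.null(features)) features <- intersect(colnames(tm), colnames(am))
  means <- colMeans(tm[, features, drop = FALSE], na.rm = TRUE)
  allmiss <- names(means)[is.nan(means)]
  if (length(allmiss))
    stop("feature(s) entirely missing in the training data: ",
         paste(allmiss, collapse = ", "))
  for (f in features) {
    na <- is.na(am[, f])
    if (any(na)) am[na, f] <- means[[f]]
  }
  out <- apply_table
  out@features <- am
  list(table = out, means = means)
}

## univariate discrimination of one feature against the labels,
## orientation-free (the better of the two directions)
.univariatePerformance <- function(x, labels, measure = c("auc01", "auc")) {
  measure <- match.arg(measure)
  ok <- !is.na(x)
  x <- x[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2L) return(NA_real_)
  r1 <- rocCurve(x, labels)
  r2 <- rocCurve(-x, labels)
  if (measure == "auc") max(r1$auc, r2$auc)
  else max(r1$pauc01, r2$pauc01)
}

#' Spearman-correlation feature deselection
#'
#' Repeatedly finds pairs of retained features whose mutual Spearman
#' correlation reaches the threshold in absolute value and drops the
#' member with the lower univariate performance against the labels
#' (partial AUC at FPR 0.1 by default), until no violating pair
#' remains. Deterministic: features are processed in canonical name
#' order and performance ties drop the later name.
#'
#' @param table FeatureTable (or numeric matrix).
#' @param labels binary labels (taken from the table when omitted).
#' @param threshold absolute Spearman correlation at or above which a
#'   pair is considered redundant (default 0.7).
#' @param measure univariate criterion, "auc01" (default) or "auc".
#' @param features candidate columns (default all).
#' @return character vector of retained feature names, with the dropped
#'   ones in attribute \code{"dropped"}.
#' @export
correlationFilter <- function(table, labels = NULL, threshold = 0.7,
                              measure = c("auc01", "auc"), features = NULL) {
  measure <- match.arg(measure)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  m <- if (is(table, "FeatureTable")) featureMatrix(table) else table
  if (is.null(labels)) labels <- peptideLabels(table)
  if (is.null(features)) features <- colnames(m)
  feats <- sort(features)
  if (length(feats) < 2L) return(feats)

  perf <- vapply(feats, function(f)
    .univariatePerformance(m[, f], labels, measure), numeric(1))
  dropped <- character()
  repeat {
    cm <- suppressWarnings(
      stats::cor(m[, feats, drop = FALSE], method = "spearman",
                 use = "pairwise.complete.obs"))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    viol <- which(abs(cm) >= threshold, arr.ind = TRUE)
    viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
    if (!nrow(viol)) break
    ## resolve the strongest correlation first
    top <- viol[which.max(abs(cm[viol])), ]
    a <- feats[top[1]]; b <- feats[top[2]]
    pa <- perf[[a]]; pb <- perf[[b]]
    loser <- if (is.na(pa) || is.na(pb)) b
             else if (pa > pb) b
             else if (pb > pa) a
             else b   # tie: drop the later name (feats is sorted)
    dropped <- c(dropped, loser)
    feats <- setdiff(feats, loser)
    if (length(feats) < 2L) break
  }
  structure(feats, dropped = dropped)
}

#' Write / read a feature table as TSV
#'
#' The written file round-trips: identifiers, label and all feature
#' columns are preserved to full double precision.
#'
#' @param table a FeatureTable.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  df <- cbind(peptideInfo(table), label = peptideLabels(table),
              as.data.frame(featureMatrix(table)))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  info_cols <- intersect(c("peptide_id", "patient_id", "mut_seq", "hla"),
                         names(df))
  feat_cols <- setdiff(names(df), c(info_cols, "label"))
  m <- as.matrix(df[feat_cols])
  mode(m) <- "numeric"
  rownames(m) <- df$peptide_id
  meta <- data.frame(feature = colnames(m),
                     category = unname(FEATURE_CATEGORIES[colnames(m)]),
                     missing_rate = colMeans(is.na(m)),
                     row.names = NULL, stringsAsFactors = FALSE)
  meta$category[is.na(meta$category)] <- "external"
  new("FeatureTable", info = df[info_cols], features = m,
      labels = .normalizeLabels(df$label), featureMeta = meta)
}
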