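## Mutation-context and patient-level (tumor microenvironment) features.

#' RNA support coefficient for a called mutation
#'
#' Proportion of variant-supporting reads among the reads covering the
#' variant position, damped by a +100 pseudo-denominator so that poorly
#' covered positions cannot reach high values:
#' n_variant / (n_coverage + 100).
#'
#' @param n_variant,n_coverage non-negative integer read counts
#'   (vectorized); \code{n_variant <= n_coverage}.
#' @return numeric in [0, 1).
#' @export
#' @examples
#' valMutRnaCoef(10, 90)  # 0.05263
valMutRnaCoef <- function(n_variant, n_coverage) {
  if (any(n_variant < 0, na.rm = TRUE) || any(n_coverage < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  if (any(n_variant > n_coverage, na.rm = TRUE))
    stop("variant reads cannot exceed coverage")
  n_variant / (n_coverage + 100)
}

#' RNA validation status of a mutation
#'
#' @param n_variant,n_coverage read counts (vectorized).
#' @param min_coverage minimum coverage to call the position assessable.
#' @return character vector among "validated", "not_found", "insufficient".
#' @export
rnaValidationStatus <- function(n_variant, n_coverage, min_coverage = 1L) {
  ifelse(n_coverage < min_coverage, "insufficient",
         ifelse(n_variant >= 1L, "validated", "not_found"))
}

#' Cytolytic activity (CYT)
#'
#' Geometric mean of GZMA and PRF1 expression, with an optional
#' pseudocount guarding against zero TPM.
#'
#' @param gzma_tpm,prf1_tpm TPM values (vectorized).
#' @param pseudocount added to both before the geometric mean
#'   (default 0.01).
#' @return numeric CYT score.
#' @export
cytolyticActivity <- function(gzma_tpm, prf1_tpm, pseudocount = 0.01) {
  if (any(gzma_tpm < 0, na.rm = TRUE) || any(prf1_tpm < 0, na.rm = TRUE))
    stop("TPM values must be non-negative")
  sqrt((gzma_tpm + pseudocount) * (prf1_tpm + pseudocount))
}

#' Marker-gene abundance scores for immune/stromal cell populations
#'
#' For each population, the mean of (by default) log2(TPM + 1) over that
#' population's marker genes present in the expression profile.
#' Populations with no measured marker gene yield NA.
#'
#' @param expression named numeric vector, gene symbol -> TPM.
#' @param marker_sets named list, population -> character vector of
#'   marker genes (default an illustrative two-marker panel per
#'   population; supply the marker list of your deconvolution tool of
#'   choice for real data).
#' @param log_transform apply log2(TPM + 1) before averaging.
#' @return named numeric vector, one score per population.
#' @export
markerPopulationScores <- function(expression,
                                   marker_sets = DEFAULT_MARKER_SETS,
                                   log_transform = TRUE) {
  if (!length(marker_sets)) stop("marker_sets must be a non-empty list")
  if (any(!vapply(marker_sets, length, 1L)))
    stop("every marker set must contain at least one gene")
  vapply(marker_sets, function(genes) {
    present <- intersect(genes, names(expression))
    if (!length(present)) return(NA_real_)
    v <- expression[present]
    if (log_transform) v <- log2(v + 1)
    mean(v)
  }, numeric(1))
}

#' Mean abundance over the estimated cell populations
#'
#' @param scores named numeric vector from
#'   \code{\link{markerPopulationScores}}.
#' @return arithmetic mean of the non-missing population scores, or NA
#'   when all are missing.
#' @export
mcpMean <- function(scores) {
  if (all(is.na(scores))) return(NA_real_)
  mean(scores, na.rm = TRUE)
}

#' Class-I HLA expression
#'
#' Aggregate TPM over the classical class-I loci (default HLA-A/B/C,
#' summed; set \code{aggregate = "mean"} for the per-locus average).
#'
#' @param expression named numeric vector, gene symbol -> TPM.
#' @param hla_genes loci to aggregate.
#' @param aggregate "sum" (default) or "mean".
#' @return numeric, or NA when none of the loci are measured.
#' @export
hlaExpression <- function(expression, hla_genes = DEFAULT_HLA_GENES,
                          aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  present <- intersect(hla_genes, names(expression))
  if (!length(present)) return(NA_real_)
  v <- expression[present]
  if (aggregate == "sum") sum(v) else mean(v)
}

#' Patient-level tumor-microenvironment feature bundle
#'
#' Convenience wrapper computing CYT, the per-population marker scores,
#' their mean, and HLA expression from one patient's expression profile.
#'
#' @param expression named numeric vector, gene symbol -> TPM.
#' @param marker_sets passed to \code{\link{markerPopulationScores}}.
#' @param pseudocount passed to \code{\link{cytolyticActivity}}.
#' @return list with elements \code{cyt}, \code{population_scores},
#'   \code{mcp_mean}, \code{hla_exp}.
#' @export
tmeFeatures <- function(expression, marker_sets = DEFAULT_MARKER_SETS,
                        pseudocount = 0.01) {
  gz <- if ("GZMA" %in% names(expression)) expression[["GZMA"]] else NA_real_
  pr <- if ("PRF1" %in% names(expression)) expression[["PRF1"]] else NA_real_
  scores <- markerPopulationScores(expression, marker_sets)
  list(cyt = if (is.na(gz) || is.na(pr)) NA_real_
             else cytolyticActivity(gz, pr, pseudocount),
       population_scores = scores,
       mcp_mean = mcpMean(scores),
       hla_exp = hlaExpression(expression))
}
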