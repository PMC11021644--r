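## Sequence-derived descriptors of a neopeptide candidate. All functions
## operate on plain upper-case amino-acid strings (20-letter alphabet;
## "X" is tolerated only inside predicted binding cores, where it marks
## the inserted wildcard position of an 8-mer core: it contributes 0 to
## scale means and is excluded from class proportions).

.splitSeq <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

.checkSeq <- function(seq, allow_x = FALSE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a single non-empty string")
  chars <- .splitSeq(seq)
  ok <- AA_ALPHABET
  if (allow_x) ok <- c(ok, "X")
  bad <- setdiff(chars, ok)
  if (length(bad))
    stop("invalid residue(s) in ", what, ": ", paste(unique(bad), collapse = ", "))
  chars
}

#' Non-anchor subsequence of a predicted binding core
#'
#' Extracts the TCR-facing stretch of a 9-residue MHC binding core: the
#' fourth to the penultimate residue (core positions 4-8). Anchor
#' positions (typically 2 and 9) are buried in the MHC groove, so core
#' physicochemistry features are computed on this window.
#'
#' @param core9 9-character binding core (may contain "X" for the
#'   inserted wildcard position of an 8-mer core).
#' @return 5-character string, core positions 4-8.
#' @export
#' @examples
#' nonAnchorSubsequence("ABCDEFGHI")  # "DEFGH"
nonAnchorSubsequence <- function(core9) {
  if (!is.character(core9) || length(core9) != 1L || nchar(core9) != 9L)
    stop("binding core must be a single 9-residue string, got length ",
         if (is.character(core9) && length(core9) == 1L) nchar(core9) else "?")
  substr(core9, 4L, 8L)
}

#' Mean residue hydrophobicity
#'
#' Arithmetic mean of a per-residue hydropathy scale over a peptide.
#' \code{HydroAll} is this value over the full mutant peptide and
#' \code{HydroCore} over \code{\link{nonAnchorSubsequence}} of its
#' binding core. Wildcard "X" residues contribute 0.
#'
#' @param seq amino-acid string.
#' @param scale named numeric map residue -> value; default Kyte-Doolittle.
#' @return numeric mean.
#' @export
hydrophobicityMean <- function(seq, scale = KD_HYDROPATHY) {
  chars <- .checkSeq(seq, allow_x = TRUE)
  vals <- ifelse(chars == "X", 0, scale[chars])
  if (anyNA(vals)) {
    bad <- unique(chars[is.na(vals)])
    stop("residue(s) not covered by the hydrophobicity scale: ",
         paste(bad, collapse = ", "))
  }
  mean(vals)
}

#' Proportion of residues belonging to a physicochemical class
#'
#' @param seq amino-acid string (wildcard "X" residues are excluded from
#'   both numerator and denominator).
#' @param residues character vector, the residue class.
#' @return proportion in [0,1].
#' @export
#' @examples
#' classProportion("AVFWKDEST", RESIDUE_CLASSES$hydro_aro)  # 3/9
classProportion <- function(seq, residues) {
  chars <- .checkSeq(seq, allow_x = TRUE)
  chars <- chars[chars != "X"]
  if (!length(chars)) stop("sequence contains no scorable residues")
  mean(chars %in% residues)
}

#' Count of cysteine residues
#' @param seq amino-acid string.
#' @return integer count of C residues.
#' @export
cysCount <- function(seq) {
  chars <- .checkSeq(seq)
  sum(chars == "C")
}

#' Guruprasad instability index
#'
#' (10/L) times the sum of the published dipeptide instability weight
#' values (DIWV) over all L-1 adjacent residue pairs.
#'
#' @param seq amino-acid string of length >= 2.
#' @return numeric index (values above 40 indicate an unstable protein
#'   in the original formulation; used here as a continuous descriptor).
#' @export
instabilityIndex <- function(seq) {
  chars <- .checkSeq(seq)
  L <- length(chars)
  if (L < 2L) stop("instability index requires length >= 2")
  (10 / L) * sum(DIWV[cbind(chars[-L], chars[-1L])])
}

## net Henderson-Hasselbalch charge of a peptide at a given pH
.peptideCharge <- function(counts, pH, pka = EMBOSS_PKA) {
  pos <- 1 / (1 + 10^(pH - pka$nterm))
  neg <- 1 / (1 + 10^(pka$cterm - pH))
  for (r in names(pka$side)) {
    n <- counts[r]
    if (is.na(n) || n == 0) next
    if (r %in% pka$positive)
      pos <- pos + n / (1 + 10^(pH - pka$side[[r]]))
    else
      neg <- neg + n / (1 + 10^(pka$side[[r]] - pH))
  }
  pos - neg
}

#' Isoelectric point
#'
#' pH at which the net Henderson-Hasselbalch charge (free termini plus
#' the D, E, C, Y, H, K, R side chains) is zero, found by bisection on
#' [0, 14]. Uses the EMBOSS pKa set by default.
#'
#' @param seq amino-acid string.
#' @param pka pKa set: list with elements \code{nterm}, \code{cterm},
#'   \code{side} (named numeric) and \code{positive} (residues charged
#'   positively when protonated).
#' @param tol bisection tolerance on pH.
#' @return pH value.
#' @export
isoelectricPoint <- function(seq, pka = EMBOSS_PKA, tol = 1e-4) {
  chars <- .checkSeq(seq)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  lo <- 0; hi <- 14
  ## charge is strictly decreasing in pH: positive at 0, negative at 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.peptideCharge(counts, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Average molecular weight
#'
#' Sum of average residue masses plus one water (the two chain termini).
#'
#' @param seq amino-acid string.
#' @return mass in Daltons.
#' @export
molecularWeight <- function(seq) {
  chars <- .checkSeq(seq)
  sum(AA_MASS_FREE[chars] - WATER_MASS) + WATER_MASS
}

#' Differential agretopicity index (DAI)
#'
#' Difference between the wild-type and mutant eluted-ligand percentile
#' ranks. With the default orientation (\code{wt_minus_mut = TRUE}) a
#' positive DAI means the mutant is predicted to be presented better
#' than its wild-type counterpart.
#'
#' @param rank_el_wt,rank_el_mut percentile ranks (vectorized).
#' @param wt_minus_mut logical orientation flag.
#' @return numeric vector; NA where the wild-type rank is missing
#'   (frameshift peptides), to be mean-imputed downstream.
#' @export
dai <- function(rank_el_wt, rank_el_mut, wt_minus_mut = TRUE) {
  if (any(rank_el_mut < 0, na.rm = TRUE) || any(rank_el_wt < 0, na.rm = TRUE))
    stop("percentile ranks must be >= 0")
  d <- rank_el_wt - rank_el_mut
  if (wt_minus_mut) d else -d
}

## raw k-mer substitution kernel between two peptides: sum over k = 1..k_max
## of substitution-score products over all aligned k-mer pairs
.kmerKernel <- function(chars_a, chars_b, k_max, submat) {
  M <- submat[chars_a, chars_b, drop = FALSE]
  la <- length(chars_a); lb <- length(chars_b)
  total <- 0
  P <- M
  for (k in seq_len(k_max)) {
    if (k > 1L) {
      if (la < k || lb < k) break
      ## shift-multiply: P[i,j] becomes the product over the k-mer
      ## starting at (i,j)
      P <- P[seq_len(la - k + 1L), seq_len(lb - k + 1L), drop = FALSE] *
        M[seq.int(k, la), seq.int(k, lb), drop = FALSE]
    }
    total <- total + sum(P)
  }
  total
}

#' Self-similarity between mutant and wild-type peptide
#'
#' Normalized substitution-matrix string kernel
#' K(mut, wt) / sqrt(K(mut, mut) * K(wt, wt)), where K sums
#' substitution-score products over all aligned k-mer pairs for
#' k = 1..\code{k_max}. Identical sequences score exactly 1; values near
#' 1 mean the mutant is barely distinguishable from self.
#'
#' @param mut_seq,wt_seq amino-acid strings.
#' @param k_max maximum k-mer length (default 3).
#' @param submat substitution matrix (default BLOSUM62 from Biostrings).
#' @return similarity score, or NA if \code{wt_seq} is missing.
#' @export
selfSimilarity <- function(mut_seq, wt_seq, k_max = 3L, submat = NULL) {
  if (is.null(wt_seq) || length(wt_seq) != 1L || is.na(wt_seq) || !nzchar(wt_seq))
    return(NA_real_)
  if (k_max < 1L) stop("k_max must be >= 1")
  if (is.null(submat)) submat <- .blosum62()
  a <- .checkSeq(mut_seq, what = "mutant sequence")
  b <- .checkSeq(wt_seq, what = "wild-type sequence")
  kab <- .kmerKernel(a, b, k_max, submat)
  kaa <- .kmerKernel(a, a, k_max, submat)
  kbb <- .kmerKernel(b, b, k_max, submat)
  kab / sqrt(kaa * kbb)
}

#' Position of a missense mutation relative to the binding core
#'
#' Locates the single substitution of a missense neopeptide and maps it
#' into the predicted 9-mer binding core: categories P1..P9, or "OC"
#' when the mutated residue lies outside the core (the protruding "gap"
#' position of peptides longer than 9).
#'
#' @param mut_seq,wt_seq equal-length amino-acid strings differing at
#'   exactly one position.
#' @param core_start 0-based offset of the binding core within the peptide.
#' @return factor level among P1..P9, OC.
#' @export
mutationPosition <- function(mut_seq, wt_seq, core_start) {
  a <- .checkSeq(mut_seq, what = "mutant sequence")
  b <- .checkSeq(wt_seq, what = "wild-type sequence")
  if (length(a) != length(b))
    stop("not a missense record: sequences differ in length")
  mism <- which(a != b)
  if (length(mism) != 1L)
    stop("not a missense record: found ", length(mism),
         " mismatches, expected exactly 1")
  pos <- mism - 1L  # 0-based
  if (pos >= core_start && pos < core_start + 9L)
    paste0("P", pos - core_start + 1L)
  else
    "OC"
}

#' Classify a missense neopeptide as conserved or improved binder
#'
#' Conserved binders (CB) retain wild-type MHC presentation (wild-type
#' rank below the binder threshold) with the mutation outside the anchor
#' positions; improved binders (IB) carry an anchor mutation that
#' improves predicted binding of the mutant over the wild type.
#'
#' @param rank_el_mut,rank_el_wt eluted-ligand percentile ranks.
#' @param mut_pos category from \code{\link{mutationPosition}}.
#' @param binder_threshold rank below which a peptide counts as a binder
#'   (default 2).
#' @param anchors anchor categories (default P2, P9).
#' @return one of "CB", "IB", "other".
#' @export
classifyBinder <- function(rank_el_mut, rank_el_wt, mut_pos,
                           binder_threshold = 2, anchors = c("P2", "P9")) {
  if (mut_pos %in% anchors) {
    if (rank_el_mut < rank_el_wt) "IB" else "other"
  } else if (rank_el_wt < binder_threshold) "CB"
  else "other"
}

## mapping from input-table column names to feature-table column names
EXTERNAL_COLUMN_MAP <- c(
  rank_el_mut = "RankEL",  rank_ba_mut = "RankBA", stability = "Stability",
  netmhc_exp = "NetMHCExp", prime = "Prime", foreignness = "Foreignness",
  expression = "Expression", var_al_frac = "VarAlFrac",
  cel_prev = "CelPrev", prio_score = "PrioScore")

#' Compute all sequence-derived features for a table of peptide records
#'
#' Applies every descriptor of the default feature panel to each record:
#' hydrophobicity means (full peptide and non-anchor core window),
#' residue-class proportions, cysteine count, instability index,
#' isoelectric point, molecular weight, DAI and self-similarity, plus
#' pass-through of the external prediction columns. Records with
#' malformed sequences are skipped with a warning naming them.
#'
#' @param records data.frame with columns \code{peptide_id},
#'   \code{patient_id}, \code{mut_seq}, \code{wt_seq} (may be NA for
#'   frameshifts), \code{core9}, \code{core_start}, \code{label}, plus
#'   any of the external prediction columns
#'   (\code{rank_el_mut}, \code{rank_el_wt}, \code{rank_ba_mut},
#'   \code{stability}, \code{netmhc_exp}, \code{prime},
#'   \code{foreignness}, \code{expression}, \code{var_al_frac},
#'   \code{cel_prev}, \code{prio_score}).
#' @param hydro_scale hydropathy scale (default Kyte-Doolittle).
#' @param k_max self-similarity kernel depth.
#' @param cys_as_proportion report CysRed as a proportion instead of a
#'   count (default FALSE, a count).
#' @param dai_wt_minus_mut DAI orientation flag.
#' @return data.frame of features aligned with \code{records} rows that
#'   passed validation, with attribute \code{"skipped"} listing dropped
#'   peptide ids.
#' @export
computePeptideFeatures <- function(records, hydro_scale = KD_HYDROPATHY,
                                   k_max = 3L, cys_as_proportion = FALSE,
                                   dai_wt_minus_mut = TRUE) {
  stopifnot(is.data.frame(records))
  need <- c("peptide_id", "mut_seq", "core9")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing required column(s): ", paste(miss, collapse = ", "))

  submat <- .blosum62()
  n <- nrow(records)
  out <- vector("list", n)
  failed <- character()
  for (i in seq_len(n)) {
    rec <- records[i, ]
    res <- tryCatch({
      mut <- rec$mut_seq
      core <- rec$core9
      nonanchor <- nonAnchorSubsequence(core)
      wt <- if ("wt_seq" %in% names(rec)) rec$wt_seq else NA_character_
      has_wt <- !is.na(wt) && nzchar(wt)
      seqlen <- nchar(mut)
      cys <- cysCount(mut)
      c(HydroAll = hydrophobicityMean(mut, hydro_scale),
        HydroCore = hydrophobicityMean(nonanchor, hydro_scale),
        PropHydroAro = classProportion(mut, RESIDUE_CLASSES$hydro_aro),
        Aro = classProportion(mut, RESIDUE_CLASSES$aromatic),
        PropAro = classProportion(nonanchor, RESIDUE_CLASSES$aromatic),
        PropSmall = classProportion(nonanchor, RESIDUE_CLASSES$small),
        PropAcidic = classProportion(nonanchor, RESIDUE_CLASSES$acidic),
        PropBasic = classProportion(nonanchor, RESIDUE_CLASSES$basic),
        CysRed = if (cys_as_proportion) cys / seqlen else cys,
        Inst = instabilityIndex(mut),
        pI = isoelectricPoint(mut),
        mw = molecularWeight(mut),
        SelfSim = if (has_wt) selfSimilarity(mut, wt, k_max, submat)
                  else NA_real_)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, paste0(rec$peptide_id, " (", conditionMessage(res), ")"))
      out[i] <- list(NULL)
    } else out[[i]] <- res
  }
  keep <- !vapply(out, is.null, logical(1))
  if (any(!keep))
    warning("skipped ", sum(!keep), " record(s) with malformed sequences: ",
            paste(failed, collapse = "; "))
  feats <- as.data.frame(do.call(rbind, out[keep]))
  kept <- records[keep, , drop = FALSE]

  ## DAI from the two eluted-ligand ranks
  feats$DAI <- if (all(c("rank_el_wt", "rank_el_mut") %in% names(kept)))
    dai(kept$rank_el_wt, kept$rank_el_mut, dai_wt_minus_mut)
  else NA_real_

  ## pass-through external prediction columns
  for (src in names(EXTERNAL_COLUMN_MAP)) {
    if (src %in% names(kept))
      feats[[EXTERNAL_COLUMN_MAP[[src]]]] <- kept[[src]]
  }

  rownames(feats) <- kept$peptide_id
  attr(feats, "skipped") <- records$peptide_id[!keep]
  feats
}
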