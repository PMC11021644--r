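## Leakage-aware cross-validation partitioning. Peptides are grouped by
## patient, and patients are merged into one component whenever their
## immunogenic peptides share a sequence motif; components are then
## distributed over folds greedily. Non-immunogenic peptides simply
## inherit their patient's fold.

.kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  unique(substring(seq, seq_len(L - k + 1L), seq.int(k, L)))
}

#' Do two sequences share a contiguous k-mer?
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param k motif length (default 6).
#' @return logical.
#' @export
sharesMotif <- function(seq_a, seq_b, k = 6L) {
  if (k < 1L) stop("k must be >= 1")
  length(intersect(.kmers(seq_a, k), .kmers(seq_b, k))) > 0L
}

#' Group patients into leakage components
#'
#' Builds the graph whose nodes are patients and whose edges join
#' patients owning motif-sharing immunogenic peptides, and returns its
#' connected components. Only immunogenic peptides induce edges;
#' negatives follow their patient.
#'
#' @param records data.frame with columns patient_id, mut_seq, label.
#' @param k motif length.
#' @return named integer vector, patient_id -> component id.
#' @export
clusterPatients <- function(records, k = 6L) {
  patients <- sort(unique(records$patient_id))
  parent <- stats::setNames(seq_along(patients), patients)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[[max(ri, rj)]] <<- min(ri, rj)
  }
  pos <- records[records$label == 1L & !is.na(records$mut_seq), ]
  if (nrow(pos)) {
    ## motif -> owning patients; any motif seen in two patients merges them
    motif_patient <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(pos))) {
      pi <- match(pos$patient_id[i], patients)
      for (m in .kmers(pos$mut_seq[i], k)) {
        prev <- motif_patient[[m]]
        if (is.null(prev)) motif_patient[[m]] <- pi
        else if (prev != pi) union2(prev, pi)
      }
    }
  }
  roots <- vapply(seq_along(patients), find, integer(1))
  stats::setNames(match(roots, sort(unique(roots))), patients)
}

#' Distribute leakage components over folds
#'
#' Greedy balanced assignment: components are sorted by peptide count
#' (descending, ties by component id) and each is placed into the fold
#' currently holding the fewest peptides (ties to the lowest fold
#' index). Deterministic.
#'
#' @param records data.frame with peptide_id, patient_id, label, mut_seq.
#' @param n_folds fold count K (default 5).
#' @param motif_k motif length for \code{\link{clusterPatients}}.
#' @return a \code{\link{PartitionAssignment}}.
#' @export
assignPartitions <- function(records, n_folds = 5L, motif_k = 6L) {
  comp <- clusterPatients(records, motif_k)
  rec_comp <- comp[records$patient_id]
  sizes <- table(rec_comp)
  if (length(sizes) < n_folds)
    stop("only ", length(sizes), " leakage components for ", n_folds,
         " folds; use a smaller fold count")
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  fold_of_comp <- integer(length(sizes))
  names(fold_of_comp) <- names(sizes)
  fold_load <- integer(n_folds)
  for (i in ord) {
    f <- which.min(fold_load)
    fold_of_comp[i] <- f
    fold_load[f] <- fold_load[f] + as.integer(sizes[i])
  }
  fold <- fold_of_comp[as.character(rec_comp)]
  names(fold) <- records$peptide_id
  new("PartitionAssignment", fold = fold, nFolds = as.integer(n_folds),
      components = comp)
}

#' Deduplicate training rows against a test fold
#'
#' Removes from the training fold every peptide whose mutant sequence
#' occurs verbatim in the test fold. Duplicates confined to the
#' training fold are kept.
#'
#' @param train_ids,test_ids peptide ids of the two folds.
#' @param sequences named character vector, peptide_id -> mut_seq.
#' @return filtered train_ids.
#' @export
dedupTrain <- function(train_ids, test_ids, sequences) {
  test_seqs <- unique(sequences[test_ids])
  test_seqs <- test_seqs[!is.na(test_seqs)]
  keep <- !(sequences[train_ids] %in% test_seqs)
  train_ids[keep]
}

#' Write / read a partition file
#' @param partitions a PartitionAssignment.
#' @param path TSV path (columns peptide_id, fold).
#' @return \code{path} invisibly / a data.frame.
#' @export
writePartitions <- function(partitions, path) {
  utils::write.table(
    data.frame(peptide_id = names(foldOf(partitions)),
               fold = unname(foldOf(partitions))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
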