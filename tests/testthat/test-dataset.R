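make_records <- function() {
  data.frame(
    peptide_id = c("p1", "p2", "p3"),
    patient_id = c("A", "A", "B"),
    mut_seq = c("SIINFEKLV", "GILGFVFTL", "KVAELVHFL"),
    wt_seq = c("SIINFEKLI", "GILGFVFTI", NA),
    core9 = c("SIINFEKLV", "GILGFVFTL", "KVAELVHFL"),
    core_start = 0L,
    label = c(1L, 0L, 0L),
    rank_el_mut = c(0.2, 1.1, 0.6),
    rank_el_wt = c(1.5, 0.8, NA),
    expression = c(12, 5, 80),
    stringsAsFactors = FALSE)
}

test_that("assembly joins peptide, RNA and patient layers", {
  rec <- make_records()
  profiles <- list(
    A = c(GZMA = 4, PRF1 = 9, "HLA-A" = 10, "HLA-B" = 20, "HLA-C" = 5,
          CD3D = 1, CD3E = 3),
    B = c(GZMA = 1, "HLA-A" = 7))
  rna <- data.frame(peptide_id = c("p1", "p3"),
                    n_variant_reads = c(10, 0),
                    n_coverage_reads = c(90, 40))
  tab <- assembleFeatureTable(rec, profiles, rna)
  expect_s4_class(tab, "FeatureTable")
  expect_equal(dim(tab)[1], 3)
  m <- featureMatrix(tab)
  expect_equal(unname(m[, "ValMutRNACoef"]), c(10 / 190, NA, 0))
  expect_equal(unname(m[1, "CYT"]), sqrt(4.01 * 9.01))
  expect_equal(unname(m[1, "HLAexp"]), 35)
  expect_equal(unname(m[3, "HLAexp"]), 7)
  expect_equal(peptideLabels(tab), c(1L, 0L, 0L))
  # duplicate ids rejected with the duplicates named
  expect_error(assembleFeatureTable(rbind(rec, rec[1, ])), "p1")
  expect_error(assembleFeatureTable(rec[0, ]), "no peptide records")
  # patient B's profile lacks PRF1 and all marker genes
  expect_true(is.na(m[3, "CYT"]))
  expect_true(is.na(m[3, "MCPmean"]))
})

test_that("mean imputation uses training means and is idempotent", {
  rec <- make_records()
  tab <- assembleFeatureTable(rec)
  # {1, NA, 3} filled from its own mean
  tab@features[, "Expression"] <- c(1, NA, 3)
  cols <- c("Expression", "HydroCore", "mw", "SelfSim", "DAI")
  imp <- imputeMean(tab, features = cols)
  expect_equal(unname(featureMatrix(imp$table)[, "Expression"]), c(1, 2, 3))
  expect_equal(unname(imp$means[["Expression"]]), 2)
  # observed values never altered; re-imputation is a no-op
  again <- imputeMean(imp$table, features = cols)
  expect_identical(featureMatrix(again$table), featureMatrix(imp$table))
  # means recomputed after imputation equal the stored means
  expect_equal(colMeans(featureMatrix(imp$table)[, cols]), imp$means)
  # test fold is filled with TRAIN means, not its own
  train <- tab[1:2]; test <- tab[3]
  train@features[, "Expression"] <- c(10, 20)
  test@features[, "Expression"] <- NA
  filled <- imputeMean(train, test, features = cols)$table
  expect_equal(unname(featureMatrix(filled)[, "Expression"]), 15)
  # a feature entirely missing in training is an error naming it
  train@features[, "Expression"] <- NA
  expect_error(imputeMean(train, features = cols), "Expression")
})

test_that("correlation filter drops the weaker of a redundant pair", {
  set.seed(7)
  n <- 300
  labels <- rbinom(n, 1, 0.2)
  A <- labels + rnorm(n, 0, 0.7)          # informative
  B <- rank(A) + rnorm(n, 0, 2)           # redundant with A, noisier
  C <- rnorm(n)                           # independent noise
  stopifnot(abs(cor(A, B, method = "spearman")) > 0.9)
  m <- cbind(A = A, B = B, C = C)
  kept <- correlationFilter(m, labels, threshold = 0.7)
  expect_setequal(as.character(kept), c("A", "C"))
  expect_equal(attr(kept, "dropped"), "B")
  # exact duplicate: exactly one survives
  m2 <- cbind(A = A, A2 = A)
  kept2 <- correlationFilter(m2, labels)
  expect_length(kept2, 1)
  # all below threshold: everything retained
  kept3 <- correlationFilter(cbind(A = A, C = C), labels)
  expect_setequal(as.character(kept3), c("A", "C"))
  # column order does not matter
  kept4 <- correlationFilter(m[, c("C", "B", "A")], labels, threshold = 0.7)
  expect_setequal(as.character(kept4), as.character(kept))
})

test_that("feature table TSV round-trips", {
  tab <- assembleFeatureTable(make_records())
  path <- tempfile(fileext = ".tsv")
  writeFeatureTable(tab, path)
  back <- readFeatureTable(path)
  expect_equal(peptideInfo(back)$peptide_id, peptideInfo(tab)$peptide_id)
  expect_equal(peptideLabels(back), peptideLabels(tab))
  expect_equal(featureMatrix(back), featureMatrix(tab), tolerance = 1e-12)
})

test_that("named feature sets resolve to the documented panels", {
  expect_length(featureSet("standard"), 22)
  expect_length(featureSet("simple"), 20)
  expect_length(featureSet("tme"), 25)
  expect_false(any(c("PrioScore", "CelPrev") %in% featureSet("simple")))
  expect_true(all(c("CYT", "MCPmean", "HLAexp") %in% featureSet("tme")))
  expect_error(featureSet("nope"))
})

test_that("peptide table reader validates headers and missing markers", {
  rec <- make_records()
  rec$expression <- c("12", "-", "80")
  rec$label <- c("immunogenic", "non-immunogenic", "non-immunogenic")
  path <- tempfile(fileext = ".tsv")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readPeptideTable(path)
  expect_equal(back$label, c(1L, 0L, 0L))
  expect_equal(back$expression, c(12, NA, 80))
  expect_true(is.na(back$wt_seq[3]))
  write.table(rec[-1], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPeptideTable(path), "peptide_id")
})
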