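test_that("non-anchor subsequence is core positions 4-8", {
  expect_equal(nonAnchorSubsequence("ABCDEFGHI"), "DEFGH")
  expect_equal(nonAnchorSubsequence("AAAAAAAAA"), "AAAAA")
  expect_error(nonAnchorSubsequence("ABCDEFGH"), "9-residue")
  expect_error(nonAnchorSubsequence(c("AAAAAAAAA", "AAAAAAAAA")))
})

test_that("hydrophobicity mean matches the Kyte-Doolittle table", {
  expect_equal(hydrophobicityMean("III"), 4.5)
  expect_equal(hydrophobicityMean("RR"), -4.5)
  for (aa in AA_ALPHABET)
    expect_equal(hydrophobicityMean(aa), unname(KD_HYDROPATHY[aa]))
  # order invariance
  expect_equal(hydrophobicityMean("ILKR"), hydrophobicityMean("RKLI"))
  # wildcard contributes zero
  expect_equal(hydrophobicityMean("IXI"), (4.5 + 0 + 4.5) / 3)
  expect_error(hydrophobicityMean("AB"), "invalid residue")
})

test_that("class proportions count residues correctly", {
  expect_equal(classProportion("FWY", RESIDUE_CLASSES$aromatic), 1)
  expect_equal(classProportion("AAAA", RESIDUE_CLASSES$aromatic), 0)
  expect_equal(classProportion("AVFWKDEST", RESIDUE_CLASSES$hydro_aro), 3 / 9)
  # order invariance and [0,1] bounds on random peptides
  set.seed(5)
  for (i in 1:20) {
    p <- random_peptide(sample(8:12, 1))
    shuffled <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
    for (cls in RESIDUE_CLASSES) {
      v <- classProportion(p, cls)
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(v, classProportion(shuffled, cls))
    }
    # acidic and basic are disjoint classes on the same window
    expect_lte(classProportion(p, RESIDUE_CLASSES$acidic) +
                 classProportion(p, RESIDUE_CLASSES$basic), 1)
  }
  # peptides made only of hydrophobic/aromatic residues score 1,
  # peptides from the complement score 0
  expect_equal(classProportion("VIYFWL", RESIDUE_CLASSES$hydro_aro), 1)
  expect_equal(classProportion("ADGKRS", RESIDUE_CLASSES$hydro_aro), 0)
  # wildcard excluded from numerator and denominator
  expect_equal(classProportion("FXW", RESIDUE_CLASSES$aromatic), 1)
})

test_that("cysteine count", {
  expect_equal(cysCount("CCC"), 3)
  expect_equal(cysCount("AAA"), 0)
  expect_equal(cysCount("ACDCA"), 2)
})

test_that("instability index reproduces the published DIWV arithmetic", {
  # frozen values from an independent implementation of the same table
  expect_equal(instabilityIndex("GG"), 66.7, tolerance = 1e-6)
  expect_equal(instabilityIndex("WW"), 5.0, tolerance = 1e-6)
  expect_equal(instabilityIndex("ACDEFGHIK"), 118.5, tolerance = 1e-6)
  expect_equal(instabilityIndex("SIINFEKLV"), -17.244444, tolerance = 1e-5)
  expect_equal(instabilityIndex("GILGFVFTL"), 20.855556, tolerance = 1e-5)
  expect_equal(instabilityIndex("KVAELVHFL"), -12.066667, tolerance = 1e-5)
  expect_error(instabilityIndex("G"), "length")
})

test_that("isoelectric point solves the charge equation", {
  # termini-only peptide: closed form pI = (pKn + pKc) / 2
  expect_equal(isoelectricPoint("AAG"), (8.6 + 3.6) / 2, tolerance = 1e-3)
  # the returned pH really zeroes the net charge
  set.seed(9)
  for (i in 1:10) {
    p <- random_peptide(sample(8:12, 1))
    pi_val <- isoelectricPoint(p)
    counts <- table(factor(strsplit(p, "")[[1]], levels = AA_ALPHABET))
    expect_lt(abs(neopredict:::.peptideCharge(counts, pi_val)), 1e-3)
  }
  # adding a basic residue strictly raises the pI
  expect_gt(isoelectricPoint("AAGK"), isoelectricPoint("AAG"))
})

test_that("molecular weight matches the standard average-mass table", {
  expect_equal(molecularWeight("G"), 75.07, tolerance = 0.01)
  expect_equal(molecularWeight("GG"), 132.12, tolerance = 0.01)
  # frozen reference values
  expect_equal(molecularWeight("SIINFEKLV"), 1062.2591, tolerance = 0.01)
  expect_equal(molecularWeight("GILGFVFTL"), 966.1732, tolerance = 0.01)
  # additivity: mw(a+b) = mw(a) + mw(b) - water
  set.seed(3)
  for (i in 1:5) {
    a <- random_peptide(5); b <- random_peptide(6)
    expect_equal(molecularWeight(paste0(a, b)),
                 molecularWeight(a) + molecularWeight(b) - 18.0153,
                 tolerance = 1e-6)
  }
})

test_that("DAI is the wild-type minus mutant rank difference", {
  expect_equal(dai(5.0, 0.5), 4.5)
  expect_equal(dai(3.7, 3.7), 0)
  expect_equal(dai(0.1, 2.0), -1.9)
  expect_equal(dai(5.0, 0.5, wt_minus_mut = FALSE), -4.5)
  expect_true(is.na(dai(NA, 0.5)))
  expect_error(dai(-1, 0.5), ">= 0")
})

test_that("self-similarity kernel is normalized, symmetric and matches
          the brute-force k-mer oracle", {
  b62 <- neopredict:::.blosum62()
  expect_equal(selfSimilarity("SIINFEKLV", "SIINFEKLV"), 1.0)
  expect_true(is.na(selfSimilarity("SIINFEKLV", NA)))
  set.seed(11)
  for (i in 1:50) {
    a <- random_peptide(9)
    b <- strsplit(a, "")[[1]]
    pos <- sample(9, 1)
    b[pos] <- sample(setdiff(AA_ALPHABET, b[pos]), 1)
    b <- paste(b, collapse = "")
    v <- selfSimilarity(a, b)
    expect_equal(v, oracle_self_similarity(a, b, 3, b62), tolerance = 1e-9)
    expect_equal(v, selfSimilarity(b, a), tolerance = 1e-12)
  }
  # unequal lengths are allowed by the kernel itself
  expect_equal(selfSimilarity("SIINFEKLV", "SIINFEKL"),
               oracle_self_similarity("SIINFEKLV", "SIINFEKL", 3, b62),
               tolerance = 1e-9)
})

test_that("mutation position maps into the binding core", {
  # 10-mer, core at offset 1: mismatch at the first peptide position is
  # outside the core
  expect_equal(mutationPosition("AIINFEKLVT", "CIINFEKLVT", 1L), "OC")
  # mismatch at the core start is P1
  expect_equal(mutationPosition("ACDEFGHIKL", "AWDEFGHIKL", 1L), "P1")
  # last core position is P9
  expect_equal(mutationPosition("ACDEFGHIKL", "ACDEFGHIKW", 1L), "P9")
  expect_error(mutationPosition("AAA", "AAA", 0L), "0 mismatches")
  expect_error(mutationPosition("AWA", "AAW", 0L), "2 mismatches")
  expect_error(mutationPosition("AAAA", "AAA", 0L), "length")
})

test_that("conserved/improved binder classification follows the rank and
          anchor rules", {
  expect_equal(classifyBinder(0.5, 0.8, "P5"), "CB")
  expect_equal(classifyBinder(0.3, 8.0, "P2"), "IB")
  expect_equal(classifyBinder(0.3, 8.0, "P5"), "other")
  expect_equal(classifyBinder(8.0, 0.3, "P2"), "other")
  expect_equal(classifyBinder(0.5, 0.8, "OC"), "CB")
})

test_that("computePeptideFeatures aggregates all descriptors", {
  rec <- data.frame(
    peptide_id = c("p1", "p2", "p3"),
    patient_id = "A",
    mut_seq = c("SIINFEKLV", "GILGFVFTLK", "KVAELVHFL"),
    wt_seq = c("SIINFEKLI", NA, "KVAELVHFI"),
    core9 = c("SIINFEKLV", "ILGFVFTLK", "KVAELVHFL"),
    core_start = c(0L, 1L, 0L),
    label = c(1L, 0L, 0L),
    rank_el_mut = c(0.2, 1.1, 0.6),
    rank_el_wt = c(1.5, NA, 0.9),
    expression = c(12, 5, 80),
    stringsAsFactors = FALSE)
  f <- computePeptideFeatures(rec)
  expect_equal(nrow(f), 3)
  # frameshift record: SelfSim and DAI missing, everything else present
  expect_true(is.na(f$SelfSim[2]))
  expect_true(is.na(f$DAI[2]))
  expect_false(anyNA(f[1, c("HydroAll", "HydroCore", "PropHydroAro",
                            "Inst", "pI", "mw", "SelfSim", "DAI")]))
  expect_equal(f$DAI[1], 1.3)
  expect_equal(f$Expression, rec$expression)
  # proportion slots in [0,1]
  props <- c("PropHydroAro", "Aro", "PropAro", "PropSmall", "PropAcidic",
             "PropBasic")
  expect_true(all(f[props] >= 0 & f[props] <= 1))
  # malformed sequence is skipped with a warning naming the record
  bad <- rbind(rec, data.frame(
    peptide_id = "bad1", patient_id = "A", mut_seq = "SIINFEKL9",
    wt_seq = NA, core9 = "SIINFEKLX", core_start = 0L, label = 0L,
    rank_el_mut = 1, rank_el_wt = NA, expression = 1))
  expect_warning(f2 <- computePeptideFeatures(bad), "bad1")
  expect_equal(nrow(f2), 3)
})
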