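test_that("ROC curve and AUC match rank statistics", {
  expect_equal(rocCurve(c(2, 3, 4, 5), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(rocCurve(c(5, 4, 3, 2), c(0, 0, 1, 1))$auc, 0.0)
  expect_equal(rocCurve(c(.9, .8, .7, .6), c(1, 0, 1, 0))$auc, 0.75)
  # lower-is-positive orientation (rank-style predictors)
  expect_equal(rocCurve(c(.9, .8, .7, .6), c(0, 1, 0, 1),
                        higher_is_positive = FALSE)$auc, 0.75)
  expect_error(rocCurve(1:3, c(1, 1, 1)), "both classes")
  # AUC equals exhaustive pair counting on 100 random instances
  set.seed(17)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(n), sample(0:2, 1))   # rounding induces ties
    expect_equal(rocCurve(s, y)$auc, oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("partial AUC at FPR 0.1 has the documented extremes", {
  y <- c(rep(1, 10), rep(0, 10))
  perfect <- rocCurve(c(rep(2, 10), rep(1, 10)), y)
  expect_equal(perfect$pauc01, 0.1)
  # chance diagonal (all scores tied): triangle of area 0.1^2/2
  expect_equal(rocCurve(rep(1, 20), y)$pauc01, 0.005)
  expect_equal(partialAuc(perfect, fpr_max = 1), perfect$auc)
  expect_error(partialAuc(perfect, fpr_max = 0), "fpr_max")
  expect_error(partialAuc(perfect, fpr_max = 1.5), "fpr_max")
  # McClish normalization maps chance to 0.5 and perfect to 1
  expect_equal(partialAuc(perfect, normalized = TRUE), 1)
  expect_equal(partialAuc(rocCurve(rep(1, 20), y), normalized = TRUE), 0.5)
  # pauc01 bounded and monotone under order-preserving transforms
  set.seed(23)
  for (i in 1:20) {
    s <- rnorm(30); y2 <- rbinom(30, 1, 0.4)
    if (length(unique(y2)) < 2) next
    r <- rocCurve(s, y2)
    expect_gte(r$pauc01, 0); expect_lte(r$pauc01, 0.1)
    expect_equal(rocCurve(exp(s), y2)$pauc01, r$pauc01, tolerance = 1e-12)
  }
})

test_that("partial AUC agrees with the pROC reference on random data", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (i in 1:10) {
    n <- 80
    y <- rbinom(n, 1, 0.3); if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- rnorm(n) + y
    r <- rocCurve(s, y)
    ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
    expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(r$pauc01,
                 as.numeric(pROC::auc(ref, partial.auc = c(1, 0.9),
                                      partial.auc.focus = "specificity",
                                      partial.auc.correct = FALSE)),
                 tolerance = 1e-9)
  }
})

test_that("average precision matches hand enumeration and null
          prevalence", {
  # all positives ranked first
  expect_equal(prMetrics(c(4, 3, 2, 1), c(1, 1, 0, 0))$average_precision, 1)
  # hand-enumerated 4-point sweep: precisions 1, 2/3 at the positives
  expect_equal(prMetrics(c(.9, .8, .7, .6), c(1, 0, 1, 0))$average_precision,
               (1 + 2 / 3) / 2)
  # random scores: AP concentrates near the prevalence
  set.seed(31)
  ap <- replicate(200, {
    y <- c(rep(1, 30), rep(0, 270))
    prMetrics(rnorm(300), y)$average_precision
  })
  expect_lt(abs(mean(ap) - 0.1), 0.02)
})

test_that("DeLong test conventions, antisymmetry and bootstrap
          agreement", {
  set.seed(37)
  n <- 80
  y <- rbinom(n, 1, 0.4); y[1:2] <- c(0, 1)
  a <- rnorm(n) + y; b <- rnorm(n) + 0.4 * y
  # identical vectors: p = 1 by convention
  expect_equal(delongTest(a, a, y)$p, 1)
  # swapping the arguments negates z
  d1 <- delongTest(a, b, y); d2 <- delongTest(b, a, y)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$p, d2$p)
  expect_equal(d1$auc_a, oracle_auc(a, y), tolerance = 1e-12)
  # agreement with a 10,000-rep paired bootstrap on toy cases
  p_boot <- oracle_bootstrap_delong(a, b, y, n_boot = 10000, seed = 2)
  expect_lt(abs(d1$p - p_boot), 0.02)
})

test_that("DeLong test matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:5) {
    n <- 60
    y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
    a <- rnorm(n) + 0.8 * y; b <- rnorm(n) + 0.3 * y
    ref <- pROC::roc.test(
      pROC::roc(y, a, quiet = TRUE, direction = "<"),
      pROC::roc(y, b, quiet = TRUE, direction = "<"),
      method = "delong", paired = TRUE)
    expect_equal(delongTest(a, b, y)$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("sensitivity/specificity intersection threshold", {
  # perfectly separated: midpoint of the gap gives sens = spec = 1
  y <- c(1, 1, 0, 0)
  t0 <- sensSpecIntersection(c(.9, .8, .2, .1), y)
  cm <- confusionAt(c(.9, .8, .2, .1), y, t0)
  expect_equal(cm@tp, 2); expect_equal(cm@tn, 2)
  # symmetric toy with a known crossing, checked by exhaustive scan
  s <- c(1, 2, 3, 4, 5, 6)
  y2 <- c(0, 0, 1, 0, 1, 1)
  t1 <- sensSpecIntersection(s, y2)
  best <- Inf
  for (t in seq(0.5, 6.5, by = 0.25)) {
    sens <- mean(s[y2 == 1] >= t); spec <- mean(s[y2 == 0] < t)
    best <- min(best, abs(sens - spec))
  }
  cm1 <- confusionAt(s, y2, t1)
  sens1 <- cm1@tp / 3; spec1 <- cm1@tn / 3
  expect_equal(abs(sens1 - spec1), best)
  # lower-is-positive orientation round-trips through the sign flip
  t2 <- sensSpecIntersection(-s, y2, higher_is_positive = FALSE)
  expect_equal(t2, -t1)
  # constant scores warn and return the single candidate
  expect_warning(t3 <- sensSpecIntersection(rep(2, 4), y), "constant")
  expect_equal(t3, 2)
})

test_that("confusion matrix at a threshold counts with orientation", {
  s <- c(0.9, 0.7, 0.5, 0.5, 0.3, 0.1)
  y <- c(1, 0, 1, 0, 1, 0)
  cm <- confusionAt(s, y, 0.5)       # equal-to-threshold is positive
  expect_equal(c(cm@tp, cm@fp, cm@fn, cm@tn), c(2, 2, 1, 1))
  # below all scores: everything predicted positive
  cm2 <- confusionAt(s, y, 0)
  expect_equal(cm2@tp + cm2@fp, 6)
  # above all: everything negative
  cm3 <- confusionAt(s, y, 2)
  expect_equal(cm3@tn + cm3@fn, 6)
  # rank-style scores flip the comparison
  cm4 <- confusionAt(s, y, 0.5, higher_is_positive = FALSE)
  expect_equal(c(cm4@tp, cm4@fp), c(2, 2))
  expect_error(confusionAt(s, y, Inf), "finite")
})

test_that("MCC and accuracy reproduce printed screen statistics", {
  # screen totals: 17,520 candidates, 467 immunogenic; three published
  # predictor cutoffs
  cases <- list(
    list(pp = 8287, tp = 246, mcc = 0.02, acc = 0.53),   # rank baseline
    list(pp = 7342, tp = 274, mcc = 0.06, acc = 0.59),   # feature model
    list(pp = 6908, tp = 288, mcc = 0.08, acc = 0.61))   # + TME
  for (cs in cases) {
    cm <- confusionMatrix(tp = cs$tp, fp = cs$pp - cs$tp,
                          fn = 467 - cs$tp,
                          tn = 17520 - cs$pp - (467 - cs$tp))
    expect_equal(round(mcc(cm), 2), cs$mcc)
    expect_equal(round(accuracy(cm), 2), cs$acc)
  }
  # degenerate marginals give MCC 0 by convention
  expect_equal(mcc(confusionMatrix(5, 0, 0, 0)), 0)
  expect_equal(accuracy(confusionMatrix(5, 0, 0, 0)), 1)
  expect_equal(mcc(confusionMatrix(1, 1, 1, 1)), 0)
  expect_equal(accuracy(confusionMatrix(1, 1, 1, 1)), 0.5)
  expect_error(confusionMatrix(0, 0, 0, 0), "empty")
})

test_that("per-patient top-k capture", {
  pats <- c("A", "A", "A", "A", "B", "B", "C")
  s <- c(.9, .8, .2, .1, .5, .4, .3)
  y <- c(1, 0, 1, 0, 1, 1, 0)
  frac <- perPatientTopK(s, y, pats, k = 2)
  expect_equal(unname(frac["A"]), 0.5)   # one of A's two positives in top 2
  expect_equal(unname(frac["B"]), 1.0)   # k covers all of B's peptides
  expect_true(is.na(frac["C"]))          # no positives -> undefined
  # k at least the patient's peptide count always captures everything
  expect_equal(unname(perPatientTopK(s, y, pats, k = 10)[c("A", "B")]),
               c(1, 1))
  expect_error(perPatientTopK(s, y, pats, k = 0), "k must be")
})
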