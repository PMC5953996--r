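test_that("classification tie rules follow the clinical conventions", {
  # flow indices: strictly below; an MFR exactly at the cutoff is normal
  expect_false(classifyAbnormal(2.1, 2.1, "strictly_below"))
  expect_true(classifyAbnormal(1.99, 2.0, "strictly_below"))
  # FFR: at or below; 0.8 exactly is hemodynamically significant
  expect_true(classifyAbnormal(0.8, 0.8, "at_or_below"))
  expect_false(classifyAbnormal(0.81, 0.8, "at_or_below"))
  expect_error(classifyAbnormal(NaN, 2), "finite")
})

test_that("diagnostic metrics and their degenerate cases", {
  perfect <- diagnosticMetrics(list(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(unlist(perfect), c(
    sensitivity = 100, specificity = 100,
    accuracy = 100, ppv = 100, npv = 100
  ))

  # zero-denominator rates are NA, never 0
  noPos <- diagnosticMetrics(list(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_true(is.na(noPos$sensitivity))
  expect_true(is.na(noPos$ppv))
  expect_equal(noPos$specificity, 100)

  expect_error(diagnosticMetrics(list(tp = 0, fp = 0, fn = 0, tn = 0)), "total")
})

test_that("accuracy is a prevalence-weighted mix of sensitivity/specificity", {
  set.seed(31)
  for (i in 1:20) {
    tab <- as.list(setNames(rpois(4, 8) + 1, c("tp", "fp", "fn", "tn")))
    m <- diagnosticMetrics(tab)
    expect_gte(m$accuracy, min(m$sensitivity, m$specificity))
    expect_lte(m$accuracy, max(m$sensitivity, m$specificity))
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 100))
  }
})

test_that("Cohen's kappa: perfect, chance, and scale invariance", {
  expect_equal(cohenKappa(list(tp = 9, fp = 0, fn = 0, tn = 21)), 1)
  expect_equal(cohenKappa(list(tp = 25, fp = 25, fn = 25, tn = 25)), 0)
  # kappa = 1 iff off-diagonals vanish
  expect_lt(cohenKappa(list(tp = 9, fp = 1, fn = 0, tn = 20)), 1)
  # invariant under multiplying all cells by a positive integer
  t1 <- list(tp = 3, fp = 2, fn = 4, tn = 11)
  t5 <- lapply(t1, `*`, 5L)
  expect_equal(cohenKappa(t1), cohenKappa(t5), tolerance = 1e-12)
  # degenerate margins
  expect_true(is.na(cohenKappa(list(tp = 10, fp = 0, fn = 0, tn = 0))))
})

test_that("ROC sweep equals Mann-Whitney pairwise concordance", {
  expect_equal(rocCurve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(rocCurve(rep(2, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))$auc, 0.5)
  expect_error(rocCurve(1:4, rep(TRUE, 4)), "both")

  set.seed(17)
  for (i in 1:10) {
    n <- 50
    truth <- runif(n) < 0.3
    if (all(truth) || !any(truth)) next
    # discretized scores so ties occur
    scores <- round(rnorm(n, mean = ifelse(truth, 1.5, 2.5)), 1)
    roc <- rocCurve(scores, truth)
    expect_equal(roc$auc, mannWhitneyAuc(scores, truth), tolerance = 1e-12)
  }
})

test_that("Youden cutoff prefers the smallest among ties", {
  # scores 1, 2 abnormal; 3, 4 normal; any cutoff in (2, 3] is optimal
  roc <- rocCurve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc$bestCutoff, 3)
  expect_true(all(c(1, 2) < roc$bestCutoff))
  expect_true(all(c(3, 4) >= roc$bestCutoff))
})

test_that("Bland-Altman bias and limits of agreement", {
  ba0 <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loaLow, 0)
  expect_equal(ba0$loaHigh, 0)

  # differences {+1, -1}: sd = sqrt(2), limits at +/- 1.96 sqrt(2)
  ba <- blandAltman(c(2, 2), c(1, 3))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loaHigh, 1.96 * sqrt(2))

  # translation equivariance
  x <- rnorm(20)
  y <- rnorm(20)
  b1 <- blandAltman(x, y)
  b2 <- blandAltman(x, y - 0.7)
  expect_equal(b2$bias, b1$bias + 0.7)
  expect_equal(b2$loaHigh - b2$loaLow, b1$loaHigh - b1$loaLow)

  expect_error(blandAltman(1:3, 1:4), "equal length")
})

test_that("Pearson correlation wrapper validates its input", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(pearsonR(x, 2 * x + 1), 1)
  expect_equal(pearsonR(x, -x), -1)
  # fixed 10-pair table vs the direct product-moment formula
  set.seed(4)
  y <- x + rnorm(10)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonR(x, y), num / den, tolerance = 1e-12)
  expect_true(is.na(pearsonR(rep(1, 5), 1:5)))
  expect_error(pearsonR(1:2, 1:2), "at least 3")
})

test_that("concordance report is consistent on a linked noiseless cohort", {
  # FFR distributions separated so disease status and FFR class coincide;
  # noiseless quantification then classifies every territory correctly
  cfg <- simConfig(
    seed = 14, nPatients = 8,
    ffrNormalMean = 0.92, ffrNormalSd = 0.01,
    ffrDiseasedMean = 0.68, ffrDiseasedSd = 0.01
  )
  study <- simulateStudy(cfg)
  spectAll <- NULL
  petAll <- NULL
  for (pat in study$patients) {
    s <- quantifySpect(pat$spect$rest, pat$spect$stress)
    p <- quantifyPet(pat$pet$rest, pat$pet$stress)
    s$patient_id <- pat$id
    p$patient_id <- pat$id
    spectAll <- rbind(spectAll, s)
    petAll <- rbind(petAll, p)
  }
  ffr <- study$truth[, c("patient_id", "territory", "ffr")]
  rep <- concordanceReport(spectAll, petAll, ffr)

  expect_equal(rep$nTerritories, 24L)
  expect_equal(rep$czt$metrics$accuracy, 100)
  expect_equal(rep$pet$metrics$accuracy, 100)
  expect_equal(rep$czt$discordant, 0)
  expect_equal(rep$pet$kappa, 1)

  # unmatched keys are named
  bad <- ffr
  bad$patient_id[1] <- "P999"
  expect_error(
    concordanceReport(spectAll, petAll, bad),
    "P999"
  )
})
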