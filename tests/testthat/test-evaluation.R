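# Independent brute-force metric tally used to cross-check the report.
bruteMetrics <- function(true, pred, nc) {
  conf <- matrix(0L, nc, nc)
  for (i in seq_along(true))
    conf[true[i] + 1, pred[i] + 1] <- conf[true[i] + 1, pred[i] + 1] + 1L
  prec <- rec <- numeric(nc)
  for (k in seq_len(nc)) {
    tp <- conf[k, k]
    prec[k] <- if (sum(conf[, k]) > 0) tp / sum(conf[, k]) else 0
    rec[k] <- if (sum(conf[k, ]) > 0) tp / sum(conf[k, ]) else 0
  }
  list(conf = conf, precision = prec, recall = rec,
       acc = mean(true == pred))
}

test_that("report metrics agree with an independent brute-force tally", {
  set.seed(61)
  for (rep in 1:3) {
    nc <- sample(3:8, 1)
    n <- 500
    true <- sample(0:(nc - 1), n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.7, true, sample(0:(nc - 1), n, TRUE))
    ref <- bruteMetrics(true, pred, nc)
    got <- evalReportFromConfusion(confusionMatrix(true, pred, nc))
    expect_equal(unname(unclass(got@confusion)), unclass(ref$conf),
                 ignore_attr = TRUE)
    expect_equal(got@perClass$precision, ref$precision)
    expect_equal(got@perClass$recall, ref$recall)
    expect_equal(got@overallAccuracy, ref$acc)
    expect_equal(got@misclassified, sum(true != pred))
  }
})

test_that("report invariants hold: row sums, trace, F1 and macro definitions", {
  set.seed(62)
  true <- sample(0:3, 300, TRUE)
  pred <- sample(0:3, 300, TRUE)
  r <- evalReportFromConfusion(confusionMatrix(true, pred, 4))
  expect_equal(unname(rowSums(r@confusion)), as.numeric(r@perClass$support))
  expect_equal(sum(diag(r@confusion)) / sum(r@confusion), r@overallAccuracy)
  expect_equal(r@misclassified, sum(r@confusion) - sum(diag(r@confusion)))
  pc <- r@perClass
  expect_equal(pc$f1, ifelse(pc$precision + pc$recall > 0,
                             2 * pc$precision * pc$recall /
                               (pc$precision + pc$recall), 0))
  expect_equal(r@macroRecall, mean(pc$recall[pc$support > 0]))
})

test_that("published count arithmetic: recall and accuracy print as reported", {
  conf <- matrix(c(77189, 0, 77501 - 77189, 0), 2, 2)
  r <- evalReportFromConfusion(conf)
  expect_equal(formatPercent(r@perClass$recall[1], 3), "99.597")
  confAll <- matrix(0, 2, 2)
  confAll[1, 1] <- 92679
  confAll[1, 2] <- 93929 - 92679
  rAll <- evalReportFromConfusion(confAll)
  expect_equal(formatPercent(rAll@overallAccuracy, 2), "98.67")
})

test_that("a perfect predictor yields an identity-structured confusion table", {
  set.seed(63)
  true <- rep(0:2, c(5, 7, 9))
  r <- evalReportFromConfusion(confusionMatrix(true, true, 3))
  expect_equal(unname(diag(r@confusion)), c(5, 7, 9))
  expect_equal(sum(r@confusion) - sum(diag(r@confusion)), 0)
  expect_equal(r@overallAccuracy, 1)
  expect_equal(r@misclassified, 0L)
})

test_that("zero-support classes are excluded from macro averages", {
  conf <- matrix(0, 3, 3)
  conf[1, 1] <- 10
  conf[2, 1] <- 10   # class 1 always confused, class 2 absent
  r <- evalReportFromConfusion(conf)
  expect_equal(r@macroRecall, mean(c(1, 0)))  # only classes with support
  expect_equal(r@perClass$support[3], 0L)
})

test_that("evaluateModel agrees with predictClass tallied by hand", {
  profs <- balancedProfiles(3, noiseScale = 0)
  dir <- makeCorpus(profs[1], nRecords = 2, beatsPerRecord = 30, seed = 64)
  ds <- integrateDatabases(list(file.path(dir, "mitdb")),
                           preprocessor = "self")
  sp <- stratifiedSplit(ds, 0.3, seed = 1)
  net <- buildFcNetwork(260, 3, hiddenUnits = 32, seed = 1)
  net <- trainModel(net, sp@train, trainConfig(maxEpochs = 10, batchSize = 20,
                                               seed = 2))
  r <- evaluateModel(net, sp@test)
  pred <- predictClass(net, sp@test)
  expect_equal(r@overallAccuracy, mean(pred == beatLabels(sp@test)))
  expect_equal(sum(r@confusion), nBeats(sp@test))
})

test_that("duplicate methods in a comparison are deduplicated with a warning", {
  profs <- balancedProfiles(2, noiseScale = 0)
  dir <- makeCorpus(profs[1], nRecords = 1, beatsPerRecord = 30, seed = 65)
  cfg <- trainConfig(maxEpochs = 2, batchSize = 20, seed = 1)
  expect_warning(
    tab <- comparePreprocessing(list(file.path(dir, "mitdb")),
                                c("none", "self", "none"), cfg,
                                nClasses = 2, splitSeed = 3),
    "duplicate")
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$method, c("none", "self"))
  expect_length(attr(tab, "reports"), 2)
})

test_that("holdout of a training-like database scores near training accuracy; shuffled labels near chance", {
  profs <- balancedProfiles(4, noiseScale = 0)
  dir <- makeCorpus(profs[1], nRecords = 3, beatsPerRecord = 50, seed = 66)
  dbPath <- file.path(dir, "mitdb")
  ds <- integrateDatabases(list(dbPath), preprocessor = "self")
  net <- buildFcNetwork(260, 4, seed = 1)
  net <- trainModel(net, ds, trainConfig(maxEpochs = 15, batchSize = 50,
                                         seed = 2))
  r <- holdoutDatabaseEval(net, dbPath)
  expect_gte(r@overallAccuracy, 0.95)

  shuffled <- ds
  set.seed(4)
  shuffled@labels <- sample(shuffled@labels)
  rs <- evaluateModel(net, shuffled)
  expect_lt(rs@overallAccuracy, 0.45)   # ~ class-prior level for 4 classes
  expect_gt(rs@overallAccuracy, 0.05)
})
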