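test_that("the FC network has five weighted layers with the stated shapes", {
  net <- buildFcNetwork(inputUnits = 260, nClasses = 16)
  expect_equal(layerCount(net), 5L)
  expect_equal(dim(net@params$W1), c(260L, 256L))
  expect_equal(dim(net@params$W5), c(256L, 16L))
  expect_equal(parameterCount(net),
               (260 * 256 + 256) + 3 * (256 * 256 + 256) + (256 * 16 + 16))
})

test_that("FC forward passes return probability rows summing to one", {
  net <- buildFcNetwork(inputUnits = 260, nClasses = 16, seed = 4)
  P1 <- predictProba(net, rnorm(260))
  expect_equal(dim(P1), c(1L, 16L))
  expect_lt(abs(sum(P1) - 1), 1e-6)
  set.seed(2)
  P <- predictProba(net, matrix(rnorm(7 * 260), 7))
  expect_true(all(P >= 0))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-6)
})

test_that("inference is deterministic (dropout disabled)", {
  net <- buildFcNetwork(inputUnits = 40, nClasses = 4, seed = 3)
  X <- matrix(rnorm(10 * 40), 10)
  expect_identical(predictProba(net, X), predictProba(net, X))
})

test_that("a zero learning rate leaves the parameters unchanged after an epoch", {
  set.seed(5)
  ds <- beatDataset(matrix(rnorm(30 * 20), 30), rep(0:2, 10))
  net <- buildFcNetwork(inputUnits = 20, nClasses = 3, hiddenUnits = 8,
                        seed = 1)
  before <- net@params
  trained <- trainModel(net, ds, trainConfig(learningRate = 0, maxEpochs = 1,
                                             batchSize = 10, seed = 2))
  nms <- grep("^[Wb]", names(before), value = TRUE)
  for (nm in nms) expect_equal(trained@params[[nm]], before[[nm]])
})

test_that("training is fully seeded: identical configs give identical histories", {
  set.seed(6)
  ds <- beatDataset(matrix(rnorm(60 * 20), 60), rep(0:3, 15))
  cfg <- trainConfig(maxEpochs = 3, batchSize = 16, seed = 7,
                     validationFraction = 0.2)
  n1 <- trainModel(buildFcNetwork(20, 4, hiddenUnits = 16, seed = 1), ds, cfg)
  n2 <- trainModel(buildFcNetwork(20, 4, hiddenUnits = 16, seed = 1), ds, cfg)
  expect_identical(history(n1), history(n2))
  expect_identical(n1@params, n2@params)
  expect_true(all(c("val_loss", "val_accuracy") %in% names(history(n1))))
})

test_that("the FC network fits a separable-by-construction 4-class corpus", {
  profs <- balancedProfiles(4, noiseScale = 0)
  dir <- makeCorpus(profs[1:2], nRecords = 2, beatsPerRecord = 40, seed = 51)
  ds <- integrateDatabases(as.list(dbPaths(dir, profs[1:2])),
                           preprocessor = "self")
  net <- buildFcNetwork(260, 4, seed = 1)
  net <- trainModel(net, ds, trainConfig(maxEpochs = 20, batchSize = 50,
                                         seed = 2))
  expect_gte(tail(history(net)$accuracy, 1), 0.99)
  expect_true(net@trained)
})

test_that("labels outside the class range are rejected", {
  ds <- beatDataset(matrix(rnorm(10 * 20), 10), labels = rep(5L, 10))
  net <- buildFcNetwork(20, 4, hiddenUnits = 8)
  expect_error(trainModel(net, ds, trainConfig(maxEpochs = 1, seed = 1)),
               "labels")
})

test_that("the residual network counts 12 weighted layers with channels 64/128/128", {
  net <- buildResNetwork(inputLength = 260)
  expect_equal(layerCount(net), 12L)
  expect_equal(net@channels, c(64L, 128L, 128L))
  expect_equal(net@kernelSizes, c(8L, 5L, 3L))
  # 9 block convolutions + 2 downsampling + 1 dense on the main path
  mains <- grep("^W_(b[0-9]c[0-9]|d[0-9])$", names(net@params), value = TRUE)
  expect_length(mains, 11)
  expect_true("Wfc" %in% names(net@params))
})

test_that("ResNet forward passes are finite probability rows, even on a zero beat", {
  net <- buildResNetwork(inputLength = 64, nClasses = 16,
                         channels = c(8, 12, 12), seed = 2)
  P <- predictProba(net, matrix(0, 1, 64))
  expect_true(all(is.finite(P)))
  expect_lt(abs(sum(P) - 1), 1e-6)
  P2 <- predictProba(net, matrix(rnorm(4 * 64), 4))
  expect_lt(max(abs(rowSums(P2) - 1)), 1e-6)
})

test_that("ResNet training reduces the loss and is seed-reproducible", {
  set.seed(8)
  n <- 48
  X <- matrix(rnorm(n * 32), n)
  y <- rep(0:1, each = n / 2)
  X[y == 1, 10:14] <- X[y == 1, 10:14] + 3
  ds <- beatDataset(X, y)
  cfg <- trainConfig(maxEpochs = 5, batchSize = 16, learningRate = 0.005,
                     seed = 3)
  net <- buildResNetwork(32, 2, channels = c(4, 6, 6), seed = 1)
  t1 <- trainModel(net, ds, cfg)
  h <- history(t1)
  expect_lt(tail(h$loss, 1), h$loss[1])
  t2 <- trainModel(buildResNetwork(32, 2, channels = c(4, 6, 6), seed = 1),
                   ds, cfg)
  expect_identical(history(t2), h)
})
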