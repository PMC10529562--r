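test_that("the default class map covers 16 classes bijectively with disjoint exclusions", {
  cm <- buildClassMap()
  expect_length(cm@classNames, 16)
  expect_setequal(unname(cm@codes), 0:15)
  expect_length(cm@codes, 16)  # one code per class: a bijection
  expect_length(intersect(names(cm@codes), cm@excludedCodes), 0)
  # the bundle-branch-block superclass is excluded, its subclasses mapped
  expect_true("B" %in% cm@excludedCodes)
  expect_true(all(c("L", "R") %in% names(cm@codes)))
})

test_that("duplicate code assignment is a configuration error", {
  bad <- data.frame(code = c("N", "N"), class_id = c(0, 1))
  expect_error(buildClassMap(bad), "duplicate")
})

test_that("a toy custom map labels symbols as assigned", {
  toy <- buildClassMap(data.frame(code = c("N", "V"), class_id = c(0, 12)))
  expect_equal(mapSymbols(toy, c("N", "V", "N")), c(0L, 12L, 0L))
  expect_true(is.na(mapSymbols(toy, "A")))
})

test_that("multi-database integration unifies window length and sampling frequency", {
  profs <- balancedProfiles(4)
  dir <- makeCorpus(profs, nRecords = 2, beatsPerRecord = 25, seed = 21)
  ds <- integrateDatabases(as.list(dbPaths(dir, profs)),
                           preprocessor = "self")
  expect_s4_class(ds, "BeatDataset")
  expect_equal(ncol(beatMatrix(ds)), 260)
  expect_equal(samplingRate(ds), 360)
  expect_setequal(unique(ds@sourceDb), c("mitdb", "supdb", "incartdb"))
  counts <- attr(ds, "counts")
  expect_equal(sum(counts$total), nBeats(ds))
  expect_equal(counts$total, counts$mitdb + counts$supdb + counts$incartdb)
})

test_that("merging is order-insensitive up to row permutation and counts are additive", {
  profs <- balancedProfiles(3)
  dir <- makeCorpus(profs[1:2], nRecords = 1, beatsPerRecord = 20, seed = 22)
  paths <- as.list(dbPaths(dir, profs[1:2]))
  d12 <- integrateDatabases(paths, preprocessor = "none")
  d21 <- integrateDatabases(rev(paths), preprocessor = "none")
  expect_equal(nBeats(d12), nBeats(d21))
  key <- function(d) {
    o <- order(d@sourceDb, d@sourceRecord, beatMatrix(d)[, 1],
               beatMatrix(d)[, 100])
    beatMatrix(d)[o, ]
  }
  expect_equal(key(d12), key(d21))
  c12 <- attr(d12, "counts")
  d1 <- integrateDatabases(paths[1], preprocessor = "none")
  d2 <- integrateDatabases(paths[2], preprocessor = "none")
  expect_equal(c12$total,
               attr(d1, "counts")$total + attr(d2, "counts")$total)
})

test_that("a class present in only one database appears in the merged counts", {
  pA <- databaseProfile("dbA", 360, classMix = c("0" = 1))
  pB <- databaseProfile("dbB", 360, classMix = c("0" = 0.5, "12" = 0.5))
  dir <- makeCorpus(list(pA, pB), nRecords = 1, beatsPerRecord = 30,
                    seed = 23)
  ds <- integrateDatabases(list(file.path(dir, "dbA"), file.path(dir, "dbB")),
                           preprocessor = "none")
  counts <- attr(ds, "counts")
  expect_equal(counts$dbA[counts$class_id == 12], 0)
  expect_gt(counts$dbB[counts$class_id == 12], 0)
  expect_equal(counts$total[counts$class_id == 12],
               counts$dbB[counts$class_id == 12])
})

test_that("stratified split uses max(1, floor(f * m_c)) test beats per class", {
  set.seed(30)
  sizes <- c(16, 10, 1, 2, 7)
  labs <- rep(seq_along(sizes) - 1L, sizes)
  ds <- beatDataset(matrix(rnorm(length(labs) * 8), length(labs)), labs)
  sp <- stratifiedSplit(ds, 0.2, seed = 4)
  got <- sp@perClassCounts
  expect_equal(got$test, c(3L, 2L, 0L, 1L, 1L))
  expect_equal(got$train + got$test, got$total)
  expect_equal(got$total, sizes)
  expect_equal(nBeats(sp@train) + nBeats(sp@test), length(labs))
})

test_that("splits are disjoint, exhaustive and seed-reproducible", {
  set.seed(31)
  ds <- beatDataset(matrix(rnorm(200 * 10), 200), rep(0:4, 40))
  a <- stratifiedSplit(ds, 0.2, seed = 9)
  b <- stratifiedSplit(ds, 0.2, seed = 9)
  expect_identical(beatMatrix(a@test), beatMatrix(b@test))
  expect_identical(beatMatrix(a@train), beatMatrix(b@train))
  c <- stratifiedSplit(ds, 0.2, seed = 10)
  expect_false(identical(beatMatrix(a@test), beatMatrix(c@test)))
  # disjoint + exhaustive: every original row appears exactly once
  all1 <- rbind(beatMatrix(a@train), beatMatrix(a@test))
  expect_equal(dim(all1), dim(beatMatrix(ds)))
  expect_equal(all1[order(all1[, 1]), ],
               beatMatrix(ds)[order(beatMatrix(ds)[, 1]), ])
})

test_that("pending column-wise preprocessing is fitted on train and applied to test", {
  profs <- balancedProfiles(3)
  dir <- makeCorpus(profs[1], nRecords = 2, beatsPerRecord = 40, seed = 24)
  ds <- integrateDatabases(list(file.path(dir, "mitdb")),
                           preprocessor = "standardize")
  expect_equal(ds@preprocessing$pending, "standardize")
  raw <- beatMatrix(ds)
  sp <- stratifiedSplit(ds, 0.25, seed = 2)
  trainB <- beatMatrix(sp@train)
  expect_lt(max(abs(colMeans(trainB))), 1e-10)
  expect_lt(max(abs(apply(trainB, 2, sd) - 1)), 1e-10)
  # test set transformed with train statistics, not its own
  expect_gt(max(abs(colMeans(beatMatrix(sp@test)))), 1e-10)
  expect_equal(sp@test@preprocessing$applied, "standardize")
})

test_that("dataset CSV persistence round trips beats, labels and metadata", {
  set.seed(33)
  ds <- beatDataset(matrix(rnorm(12 * 20), 12), rep(0:2, 4),
                    sourceDb = "dbX", sourceRecord = "r1",
                    classNames = paste0("c", 0:2), fs = 360)
  base <- file.path(tempfile(), "ds")
  writeBeatDataset(ds, base, seed = 99)
  ds2 <- readBeatDataset(base)
  expect_equal(beatMatrix(ds2), beatMatrix(ds), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(beatLabels(ds2), beatLabels(ds))
  expect_equal(samplingRate(ds2), 360)
  expect_equal(ds2@classNames, paste0("c", 0:2))
})
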