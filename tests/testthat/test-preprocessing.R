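test_that("standardizeColumns gives zero-mean unit-sd columns and is idempotent", {
  expect_equal(unname(standardizeColumns(matrix(c(1, 2, 3)))[, 1]),
               c(-1, 0, 1))
  set.seed(42)
  A <- matrix(rnorm(50 * 260, mean = 3, sd = 2), 50)
  S <- standardizeColumns(A)
  expect_lt(max(abs(colMeans(S))), 1e-10)
  expect_lt(max(abs(apply(S, 2, sd) - 1)), 1e-10)
  S2 <- standardizeColumns(S)
  expect_equal(unclass(S2), unclass(S), tolerance = 1e-12,
               ignore_attr = TRUE)
  B <- A; B[, 7] <- 4
  expect_error(standardizeColumns(B), "zero-variance.*7")
})

test_that("extremumScale maps columns onto [0,1], constants to 0 with a warning", {
  expect_equal(unname(extremumScale(matrix(c(0, 5, 10)))[, 1]),
               c(0, 0.5, 1))
  set.seed(7)
  A <- matrix(rnorm(40 * 30), 40)
  E <- extremumScale(A)
  expect_equal(unname(apply(E, 2, min)), rep(0, 30))
  expect_equal(unname(apply(E, 2, max)), rep(1, 30))
  B <- A; B[, 3] <- 2.5
  expect_warning(E2 <- extremumScale(B), "constant")
  expect_true(all(E2[, 3] == 0))
})

test_that("meanScale divides by the column mean and is scale-invariant", {
  expect_equal(unname(meanScale(matrix(c(2, 4, 6)))[, 1]), c(0.5, 1, 1.5))
  expect_equal(unname(meanScale(matrix(rep(1, 5)))[, 1]), rep(1, 5))
  set.seed(8)
  A <- matrix(rexp(30 * 10) + 0.1, 30)
  expect_equal(unclass(meanScale(7 * A)), unclass(meanScale(A)),
               tolerance = 1e-12, ignore_attr = TRUE)
  B <- A; B[, 2] <- c(-1, 1, rep(0, 28))
  expect_error(meanScale(B), "zero-mean")
})

test_that("stdScale divides by the column sample sd", {
  expect_equal(unname(stdScale(matrix(c(0, 2, 4)))[, 1]), c(0, 1, 2))
  set.seed(9)
  A <- matrix(rnorm(40 * 20, sd = 5), 40)
  Z <- stdScale(A)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-10)
  expect_equal(unclass(stdScale(Z)), unclass(Z), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("selfProcess normalizes each beat to zero mean and unit sd", {
  expect_equal(unname(selfProcess(matrix(c(1, 2, 3), 1))[1, ]), c(-1, 0, 1))
  set.seed(10)
  A <- matrix(rnorm(50 * 260), 50)
  P <- selfProcess(A)
  expect_lt(max(abs(rowMeans(P))), 1e-10)
  expect_lt(max(abs(apply(P, 1, sd) - 1)), 1e-10)
})

test_that("selfProcess is affine-invariant per beat and idempotent", {
  set.seed(11)
  A <- matrix(rnorm(30 * 100), 30)
  P <- selfProcess(A)
  alpha <- rexp(30) + 0.1
  beta <- rnorm(30)
  expect_equal(unclass(selfProcess(A * alpha + beta)), unclass(P),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(selfProcess(P)), unclass(P), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("flatline beats are dropped per beat, not a global failure", {
  set.seed(12)
  A <- matrix(rnorm(10 * 50), 10)
  A[4, ] <- 2.5
  P <- selfProcess(A)
  expect_equal(nrow(P), 9)
  expect_equal(attr(P, "dropped"), 4L)

  ds <- beatDataset(A, labels = rep(0L, 10), sourceRecord = paste0("r", 1:10))
  ds2 <- preprocessDataset(ds, "self")
  expect_equal(nBeats(ds2), 9)
  expect_match(dropLog(ds2)$reason, "flatline")
  expect_equal(dropLog(ds2)$record_id, "r4")
})

test_that("all operators preserve shape and labels and are deterministic", {
  set.seed(13)
  ds <- beatDataset(matrix(rnorm(20 * 40), 20), labels = rep(0:3, 5))
  for (m in setdiff(preprocessingMethods(), "none")) {
    d1 <- preprocessDataset(ds, m)
    d2 <- preprocessDataset(ds, m)
    expect_equal(dim(beatMatrix(d1)), c(20L, 40L))
    expect_identical(beatLabels(d1), beatLabels(ds))
    expect_identical(beatMatrix(d1), beatMatrix(d2))
    expect_equal(d1@preprocessing$applied, m)
  }
})

test_that("column-wise statistics fitted on one set transfer to another without refitting", {
  set.seed(14)
  A <- matrix(rnorm(60 * 20, mean = 2), 60)
  Btest <- matrix(rnorm(10 * 20, mean = 2), 10)
  S <- standardizeColumns(A)
  st <- attr(S, "stats")
  Bs <- standardizeColumns(Btest, stats = st)
  manual <- sweep(sweep(Btest, 2, st$center), 2, st$scale, "/")
  expect_equal(unclass(Bs), manual, tolerance = 1e-12, ignore_attr = TRUE)
})
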