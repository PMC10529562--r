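test_that("numOfSample follows the 60 * fs / bpm rule with its physiological bounds", {
  expect_identical(numOfSample(100, 360), 216L)
  expect_identical(numOfSample(100, 250), 150L)
  expect_identical(numOfSample(60, 360), 360L)
  expect_identical(numOfSample(60, 128), 128L)
  expect_error(numOfSample(50, 360), "60, 100")
  expect_error(numOfSample(110, 360), "60, 100")
  expect_error(numOfSample(80, -1), "positive")
})

test_that("numOfSample is decreasing in heart rate and increasing in sampling frequency", {
  hr <- 60:100
  for (fs in c(128, 250, 257, 360)) {
    v <- vapply(hr, numOfSample, 0L, fSample = fs)
    expect_true(all(diff(v) <= 0))
    expect_true(all(v >= 0.6 * fs - 0.5 & v <= fs))
  }
  for (h in c(60, 75, 100)) {
    v <- vapply(c(128, 250, 257, 360), function(f) numOfSample(h, f), 0L)
    expect_true(all(diff(v) > 0))
  }
})

test_that("splitWindow centres the window on the R peak", {
  expect_equal(splitWindow(260), c(M = 129L, N = 130L))
  expect_equal(splitWindow(3), c(M = 1L, N = 1L))
  expect_equal(splitWindow(261), c(M = 130L, N = 130L))
  expect_error(splitWindow(2), ">= 3")
  for (L in 3:300) {
    mn <- splitWindow(L)
    expect_identical(unname(mn[1] + mn[2] + 1L), L)
    expect_true((mn[[2]] - mn[[1]]) %in% c(0L, 1L))
  }
})

test_that("WindowSpec enforces the physiological L range", {
  expect_silent(validObject(windowSpec(260, 360)))
  expect_error(windowSpec(100, 360), "physiological")
  expect_error(windowSpec(400, 360), "physiological")
})

test_that("resampling preserves DC, length ratios and band-limited content", {
  y <- resampleSignal(rep(2.5, 100), 257, 360)
  expect_length(y, round(100 * 360 / 257))
  expect_lt(max(abs(y - 2.5)), 1e-12)

  expect_length(resampleSignal(rnorm(128), 128, 360), 360)

  t <- seq(0, 1 - 1 / 128, by = 1 / 128)
  s <- sin(2 * pi * 5 * t)
  y2 <- resampleSignal(s, 128, 360)
  t2 <- seq(0, by = 1 / 360, length.out = length(y2))
  interior <- 30:(length(y2) - 30)
  expect_lt(max(abs(y2 - sin(2 * pi * 5 * t2))[interior]), 1e-2)

  x <- rnorm(500)
  expect_identical(resampleSignal(x, 360, 360), x)
  expect_error(resampleSignal(numeric(0), 128, 360), "empty")
})

test_that("Fourier resampling agrees with polyphase resampling away from the edges", {
  set.seed(90)
  # band-limited test signal: sum of low-frequency sinusoids at 128 Hz
  t <- seq(0, 4 - 1 / 128, by = 1 / 128)
  x <- sin(2 * pi * 3 * t) + 0.5 * cos(2 * pi * 11 * t + 1)
  ours <- resampleSignal(x, 128, 360)
  ref <- signal::resample(x, 360, 128)
  n <- min(length(ours), length(ref))
  interior <- 100:(n - 100)
  expect_lt(max(abs(ours[interior] - ref[interior])), 0.02)
})

test_that("extractBeats reads M back and N forward from each R peak", {
  rec <- rampRecord(1000, fs = 360)
  w <- windowSpec(260, 360)
  cm <- buildClassMap()
  ann <- beatAnnotationSet(200L, "N")
  ds <- extractBeats(rec, ann, w, cm)
  expect_equal(nBeats(ds), 1)
  # 0-based window [200-129, 200+130] = [71, 330] on a 0-based ramp
  expect_equal(unname(beatMatrix(ds)[1, ]), as.numeric(71:330))
  expect_equal(beatLabels(ds), 0L)
})

test_that("boundary-crossing beats are dropped and logged; counts are conserved", {
  rec <- rampRecord(1000, fs = 360)
  w <- windowSpec(260, 360)
  cm <- buildClassMap()
  ds <- extractBeats(rec, beatAnnotationSet(100L, "N"), w, cm)
  expect_equal(nBeats(ds), 0)
  expect_equal(nrow(dropLog(ds)), 1)

  ds2 <- extractBeats(rec, beatAnnotationSet(c(200L, 500L, 900L),
                                             c("N", "N", "N")), w, cm)
  expect_equal(nBeats(ds2), 2)  # 900 + 130 > 999
  expect_equal(dropLog(ds2)$r_index, 900L)
  expect_equal(nBeats(ds2) + nrow(dropLog(ds2)), 3)

  # brute-force conservation over random annotation placements
  set.seed(12)
  for (rep in 1:5) {
    r <- sort(sample(0:999, 20))
    ann <- beatAnnotationSet(r, rep("V", 20))
    ds3 <- extractBeats(rec, ann, w, cm)
    expected <- sum(r - 129 >= 0 & r + 130 <= 999)
    expect_equal(nBeats(ds3), expected)
    expect_equal(nBeats(ds3) + nrow(dropLog(ds3)), 20)
  }
})

test_that("unmapped symbols are skipped silently, not logged as drops", {
  rec <- rampRecord(1000, fs = 360)
  ann <- beatAnnotationSet(c(300L, 400L, 500L), c("N", "+", "~"))
  ds <- extractBeats(rec, ann, windowSpec(260, 360), buildClassMap())
  expect_equal(nBeats(ds), 1)
  expect_equal(nrow(dropLog(ds)), 0)
})

test_that("records at other native frequencies yield beats of exactly L target samples", {
  w <- windowSpec(260, 360)
  cm <- buildClassMap()
  for (fs in c(128, 257)) {
    prof <- databaseProfile("x", fs, classMix = c("0" = 1),
                            baselineWander = c(0.2, 0.5, 0),
                            powerline = c(50, 0), emg = 0)
    gen <- generateRecord(prof, 8, seed = 3)
    for (path in c("beatwise", "recordwise")) {
      ds <- extractBeats(gen$record, gen$annotations, w, cm, path = path)
      expect_equal(ncol(beatMatrix(ds)), 260)
      expect_gt(nBeats(ds), 0)
      expect_equal(samplingRate(ds), 360)
    }
  }
})
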