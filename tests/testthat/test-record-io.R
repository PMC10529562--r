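test_that("WFDB round trip preserves fs, length, annotations exactly and amplitudes within quantization", {
  set.seed(71)
  sig <- matrix(rnorm(5000 * 2, sd = 1.5), ncol = 2)
  rec <- ecgRecord(sig, fs = 360, leadNames = c("MLII", "V5"),
                   recordId = "rt01", sourceDb = "testdb")
  ann <- beatAnnotationSet(c(200L, 500L, 900L, 4000L), c("N", "V", "N", "A"))
  base <- file.path(tempfile("wfdb"), "rt01")
  writeEcgRecord(rec, ann, base, gain = 200)

  rec2 <- readEcgRecord(base)
  expect_equal(samplingRate(rec2), 360)
  expect_equal(nrow(rec2@signal), 5000)
  expect_equal(leadNames(rec2), c("MLII", "V5"))
  expect_equal(rec2@sourceDb, "testdb")
  expect_lte(max(abs(rec2@signal - sig)), 1 / 200)

  ann2 <- readBeatAnnotations(base)
  expect_identical(ann2@indices, ann@indices)
  expect_identical(ann2@symbols, ann@symbols)
})

test_that("constant-zero record reads back exactly zero", {
  rec <- ecgRecord(rep(0, 800), fs = 360)
  base <- file.path(tempfile(), "zero")
  writeEcgRecord(rec, beatAnnotationSet(), base)
  expect_true(all(readEcgRecord(base)@signal == 0))
})

test_that("annotation stream handles large gaps (SKIP escapes) and empty sets", {
  ann <- beatAnnotationSet(c(10L, 900L, 200000L, 200500L),
                           c("N", "L", "/", "f"))
  rec <- ecgRecord(rep(0, 201000), fs = 360)
  base <- file.path(tempfile(), "gap")
  writeEcgRecord(rec, ann, base)
  got <- readBeatAnnotations(base)
  expect_identical(got@indices, ann@indices)
  expect_identical(got@symbols, ann@symbols)

  base2 <- file.path(tempfile(), "empty")
  writeEcgRecord(ecgRecord(rep(0, 100), fs = 250), beatAnnotationSet(), base2)
  expect_length(readBeatAnnotations(base2)@indices, 0)
})

test_that("corrupt annotation streams raise a format error with a byte offset", {
  f <- tempfile(fileext = ".atr")
  writeBin(as.raw(c(0x05, 0x04, 0x11)), f)  # odd byte count
  expect_error(ecgfuse:::readAtr(f), "corrupt.*offset")

  f2 <- tempfile(fileext = ".atr")
  con <- file(f2, "wb")
  writeBin(as.integer(c(59 * 1024, 3)), con, size = 2, endian = "little")
  close(con)  # SKIP without its 4-byte interval, no EOF
  expect_error(ecgfuse:::readAtr(f2), "corrupt")
})

test_that("lead priority selects the first available lead, falling back to lead 0", {
  sig <- cbind(MLII = rnorm(100), V5 = rnorm(100))
  rec <- ecgRecord(sig, fs = 360, leadNames = c("MLII", "V5"))
  base <- file.path(tempfile(), "leads")
  writeEcgRecord(rec, beatAnnotationSet(), base)

  r1 <- readEcgRecord(base, leadPriority = c("MLII"))
  expect_equal(leadNames(r1), "MLII")
  expect_equal(r1@provenance$selectedLead, "MLII")

  r2 <- readEcgRecord(base, leadPriority = c("V4", "V5"))
  expect_equal(leadNames(r2), "V5")  # second priority

  r3 <- readEcgRecord(base, leadPriority = c("V4", "MLIII"))
  expect_equal(leadNames(r3), "MLII")  # fallback to lead 0

  # deterministic: same priority, same choice
  expect_equal(leadNames(readEcgRecord(base, leadPriority = c("V4", "V5"))),
               "V5")
})

test_that("CSV fallback round trip is exact", {
  set.seed(5)
  rec <- ecgRecord(matrix(rnorm(300), ncol = 1), fs = 257, leadNames = "V4",
                   recordId = "c1", sourceDb = "incart-like")
  ann <- beatAnnotationSet(c(50L, 150L), c("N", "S"))
  base <- file.path(tempfile(), "c1")
  writeEcgRecord(rec, ann, base, format = "csv")
  rec2 <- readEcgRecord(base)
  expect_equal(rec2@signal, rec@signal, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(samplingRate(rec2), 257)
  got <- readBeatAnnotations(base)
  expect_identical(got@indices, ann@indices)
  expect_identical(got@symbols, ann@symbols)
})

test_that("generator round trip recovers exactly the planted annotations", {
  prof <- defaultProfiles()$mitdb
  gen <- generateRecord(prof, 12, seed = 31)
  base <- file.path(tempfile(), "gen")
  writeEcgRecord(gen$record, gen$annotations, base)
  expect_length(readBeatAnnotations(base)@indices, 12)
  expect_identical(readBeatAnnotations(base)@indices,
                   gen$annotations@indices)
})

test_that("missing files raise I/O errors", {
  expect_error(readEcgRecord(file.path(tempdir(), "nope")), "no record")
  expect_error(readBeatAnnotations(file.path(tempdir(), "nope")),
               "no annotation")
})
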