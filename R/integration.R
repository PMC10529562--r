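# Class-map construction, multi-database merge and stratified 8:2 splitting.

# The 16 retained heartbeat classes with their conventional single-character
# annotation codes. Superclasses subsuming retained classes (bundle branch
# block 'B') and non-beat marks are excluded rather than mapped.
.hercules16 <- data.frame(
  class_id = 0:15,
  code = c("N", "f", "e", "/", "j", "n", "L", "R",
           "S", "A", "J", "a", "V", "E", "F", "Q"),
  abbrev = c("NB", "FPNB", "AEB", "PB", "NEB", "SEB", "LBBB", "RBBB",
             "SP", "APB", "NPB", "AAPB", "PVC", "VEB", "FVNB", "UB"),
  name = c("Normal beat", "Fusion of paced and normal beat",
           "Atrial escape beat", "Paced beat",
           "Nodal (junctional) escape beat", "Supraventricular escape beat",
           "Left bundle branch block beat", "Right bundle branch block beat",
           "Supraventricular premature", "Atrial premature beat",
           "Nodal (junctional) premature beat",
           "Aberrated atrial premature beat",
           "Premature ventricular contraction", "Ventricular escape beat",
           "Fusion of ventricular and normal beat", "Unclassifiable beat")
)
.hercules16Excluded <- c("B", "r", "?", "+", "~", "|", "\"", "s", "T", "*",
                         "D", "=", "p", "t", "u", "!", "[", "]", "@", "x",
                         "(", ")", "^")

#' Build a beat-code to class-id map
#'
#' The default `"hercules16"` scheme maps the conventional single-character
#' beat codes onto 16 classes (normal, paced, escape, premature, bundle
#' branch block, ventricular, fusion and unclassifiable beats). Parent codes
#' that subsume retained classes (e.g. the generic bundle-branch-block code
#' `B`, which contains `L` and `R`) and non-beat marks are excluded. A custom
#' map may be given as a data.frame with columns `code`, `class_id` and
#' optionally `abbrev`/`name`.
#'
#' @param scheme `"hercules16"` (default) or a custom data.frame.
#' @param excludedCodes Codes to exclude explicitly (defaults to the scheme's
#'   own exclusion list).
#' @return A validated [ClassMap-class].
#' @examples
#' cm <- buildClassMap()
#' length(cm@classNames)  # 16
#' @export
buildClassMap <- function(scheme = "hercules16", excludedCodes = NULL) {
  if (is.character(scheme) && length(scheme) == 1) {
    if (scheme != "hercules16")
      stop("unknown scheme '", scheme, "'", call. = FALSE)
    tab <- .hercules16
    if (is.null(excludedCodes)) excludedCodes <- .hercules16Excluded
    name <- "hercules16"
  } else {
    tab <- as.data.frame(scheme)
    if (!all(c("code", "class_id") %in% names(tab)))
      stop("custom scheme needs columns 'code' and 'class_id'", call. = FALSE)
    if (anyDuplicated(tab$code))
      stop("duplicate code assignment: ",
           paste(unique(tab$code[duplicated(tab$code)]), collapse = " "),
           call. = FALSE)
    if (is.null(tab$abbrev)) tab$abbrev <- paste0("C", tab$class_id)
    if (is.null(tab$name)) tab$name <- tab$abbrev
    if (is.null(excludedCodes)) excludedCodes <- character(0)
    name <- "custom"
  }
  if (anyDuplicated(tab$code))
    stop("duplicate code assignment", call. = FALSE)
  nClasses <- max(tab$class_id) + 1L
  classNames <- rep(NA_character_, nClasses)
  classAbbrev <- rep(NA_character_, nClasses)
  classNames[tab$class_id + 1L] <- tab$name
  classAbbrev[tab$class_id + 1L] <- tab$abbrev
  classNames[is.na(classNames)] <- paste0("class", which(is.na(classNames)) - 1L)
  classAbbrev[is.na(classAbbrev)] <- paste0("C", which(is.na(classAbbrev)) - 1L)
  new("ClassMap", scheme = name,
      codes = stats::setNames(as.integer(tab$class_id), tab$code),
      classNames = classNames, classAbbrev = classAbbrev,
      excludedCodes = as.character(excludedCodes))
}

#' Map annotation symbols to class ids
#' @param classMap A [ClassMap-class].
#' @param symbols Character vector of beat codes.
#' @return Integer class ids; `NA` for unmapped codes.
#' @export
mapSymbols <- function(classMap, symbols) {
  stopifnot(is(classMap, "ClassMap"))
  unname(classMap@codes[symbols])
}

#' Merge beat datasets by row concatenation
#'
#' @param ... [BeatDataset-class] objects sharing beat length, sampling
#'   frequency and class scheme.
#' @return The merged [BeatDataset-class] (drop logs concatenated).
#' @export
mergeBeatDatasets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !is(parts[[1]], "BeatDataset"))
    parts <- parts[[1]]
  stopifnot(length(parts) >= 1, all(vapply(parts, is, TRUE, "BeatDataset")))
  ns <- vapply(parts, function(d) ncol(d@beats), 0L)
  if (length(unique(ns[vapply(parts, nBeats, 0L) > 0 | ns > 0])) > 1)
    stop("datasets have differing beat lengths", call. = FALSE)
  ref <- parts[[1]]
  beatDataset(
    do.call(rbind, lapply(parts, beatMatrix)),
    labels = unlist(lapply(parts, beatLabels)),
    sourceDb = unlist(lapply(parts, function(d) d@sourceDb)),
    sourceRecord = unlist(lapply(parts, function(d) d@sourceRecord)),
    classNames = ref@classNames, fs = ref@fs,
    preprocessing = ref@preprocessing,
    dropLog = do.call(rbind, lapply(parts, dropLog))
  )
}

#' Integrate multiple ECG databases into one beat dataset
#'
#' Runs the full harmonization pipeline over a list of source databases:
#' per-record lead selection, fixed-window beat extraction around annotated R
#' peaks, resampling to the unified target frequency, class-code
#' harmonization and preprocessing, then concatenates everything with
#' per-beat provenance.
#'
#' Each element of `databases` is a list with elements `records` (a list of
#' [EcgRecord-class]) and `annotations` (a parallel list of
#' [BeatAnnotationSet-class]), plus optional `leadPriority` and `name`; or a
#' character path to a database directory in [readEcgRecord()] formats.
#'
#' The self-processing operator (and "none") is applied immediately, per
#' beat. Column-wise operators depend on population statistics; with
#' `pooledStats = FALSE` (default) they are left pending and fitted on the
#' training split by [stratifiedSplit()], avoiding train/test leakage; with
#' `pooledStats = TRUE` they are fitted here on the full dataset.
#'
#' @param databases List of database descriptors (see Details).
#' @param window A [WindowSpec-class]; default 260 samples at 360 Hz.
#' @param classMap A [ClassMap-class].
#' @param preprocessor Operator name from [preprocessingMethods()].
#' @param pooledStats Fit column-wise statistics on the pooled dataset now?
#' @param extractionPath Passed to [extractBeats()].
#' @return A [BeatDataset-class]; per-class per-database counts are attached
#'   as `attr(, "counts")`.
#' @export
integrateDatabases <- function(databases, window = windowSpec(260, 360),
                               classMap = buildClassMap(),
                               preprocessor = "self", pooledStats = FALSE,
                               extractionPath = "beatwise") {
  stopifnot(length(databases) >= 1)
  preprocessor <- match.arg(preprocessor, preprocessingMethods())
  parts <- list()
  for (db in databases) {
    if (is.character(db)) {
      bases <- listRecords(db)
      name <- basename(db)
      db <- list(
        records = lapply(bases, readEcgRecord, sourceDb = name),
        annotations = lapply(bases, readBeatAnnotations),
        name = name
      )
    }
    recs <- db$records
    if (!is.null(db$leadPriority))
      recs <- lapply(recs, selectLead, leadPriority = db$leadPriority)
    if (!is.null(db$name))
      recs <- lapply(recs, function(r) { r@sourceDb <- db$name; r })
    for (i in seq_along(recs)) {
      parts[[length(parts) + 1L]] <-
        extractBeats(recs[[i]], db$annotations[[i]], window, classMap,
                     path = extractionPath)
    }
  }
  merged <- mergeBeatDatasets(parts)
  if (nBeats(merged) == 0)
    stop("integration produced no mappable beats", call. = FALSE)
  if (preprocessor %in% c("none", "self")) {
    merged <- preprocessDataset(merged, preprocessor)
  } else if (pooledStats) {
    merged <- preprocessDataset(merged, preprocessor)
  } else {
    merged@preprocessing$pending <- preprocessor
  }
  attr(merged, "counts") <- perClassCounts(merged)
  merged
}

#' Per-class, per-database beat counts
#'
#' Tabulates kept beats by class and source database, in the style of a
#' database-integration summary table (one row per class, one column per
#' database plus a total).
#'
#' @param dataset A [BeatDataset-class].
#' @return data.frame: class_id, abbrev, one column per database, total.
#' @export
perClassCounts <- function(dataset) {
  stopifnot(is(dataset, "BeatDataset"))
  nc <- max(length(dataset@classNames), max(c(dataset@labels, -1L)) + 1L)
  cls <- factor(dataset@labels, levels = 0:(nc - 1L))
  dbs <- sort(unique(dataset@sourceDb))
  tab <- table(cls, factor(dataset@sourceDb, levels = dbs))
  out <- data.frame(class_id = 0:(nc - 1L))
  cn <- dataset@classNames
  out$class <- if (length(cn) == nc) cn else paste0("class", out$class_id)
  for (d in dbs) out[[d]] <- as.integer(tab[, d])
  out$total <- as.integer(rowSums(tab))
  out
}

#' Stratified train/test split
#'
#' Splits a dataset class by class: a class with `m_c >= 2` members
#' contributes `max(1, floor(testFraction * m_c))` test beats (so every
#' multi-member class is represented in the test set), a singleton class
#' stays entirely in training. Assignment within a class is a seeded shuffle;
#' the same (dataset, fraction, seed) always gives the same split. If a
#' column-wise preprocessing operator was left pending by
#' [integrateDatabases()], its statistics are fitted on the training split
#' and applied unchanged to the test split.
#'
#' @param dataset A [BeatDataset-class].
#' @param testFraction Test proportion in (0, 1); default 0.2.
#' @param seed Integer seed for the within-class shuffles.
#' @return A [SplitResult-class].
#' @export
stratifiedSplit <- function(dataset, testFraction = 0.2, seed = 1) {
  stopifnot(is(dataset, "BeatDataset"))
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be in (0, 1)", call. = FALSE)
  seed <- as.integer(seed)
  m <- nBeats(dataset)
  if (m == 0) stop("cannot split an empty dataset", call. = FALSE)
  labs <- dataset@labels
  testIdx <- integer(0)
  rows <- list()
  withSeed(seed, {
    for (cl in sort(unique(labs))) {
      idx <- which(labs == cl)
      mc <- length(idx)
      nTest <- if (mc >= 2) max(1L, floor(testFraction * mc)) else 0L
      sel <- if (nTest > 0) sample(idx, nTest) else integer(0)
      testIdx <- c(testIdx, sel)
      rows[[length(rows) + 1L]] <-
        data.frame(class_id = cl, total = mc, train = mc - nTest,
                   test = nTest)
    }
  })
  testIdx <- sort(testIdx)
  trainIdx <- setdiff(seq_len(m), testIdx)
  counts <- do.call(rbind, rows)
  counts$class <- if (length(dataset@classNames))
    dataset@classNames[counts$class_id + 1L] else as.character(counts$class_id)
  counts <- counts[, c("class_id", "class", "total", "train", "test")]

  subsetDs <- function(idx) {
    beatDataset(dataset@beats[idx, , drop = FALSE], dataset@labels[idx],
                sourceDb = dataset@sourceDb[idx],
                sourceRecord = dataset@sourceRecord[idx],
                classNames = dataset@classNames, fs = dataset@fs,
                preprocessing = dataset@preprocessing)
  }
  train <- subsetDs(trainIdx)
  test <- subsetDs(testIdx)

  pending <- dataset@preprocessing$pending
  if (!is.null(pending) && pending != "none") {
    trainBeats <- applyPreprocessor(train@beats, pending)
    stats <- attr(trainBeats, "stats")
    train <- preprocessDataset(train, pending, stats = stats)
    test <- preprocessDataset(test, pending, stats = stats)
  }
  new("SplitResult", train = train, test = test, perClassCounts = counts,
      seed = seed, testFraction = testFraction)
}

## ---- dataset persistence ----

#' Write a BeatDataset as CSV with a JSON sidecar
#'
#' One beat per row: n amplitude columns `s0..s(n-1)`, then `label`,
#' `source_db`, `source_record`. The sidecar `<base>.meta.json` records the
#' sampling frequency, beat length, class names, preprocessing state and an
#' optional seed.
#'
#' @param dataset A [BeatDataset-class].
#' @param base Output base path (writes `<base>.csv` + `<base>.meta.json`).
#' @param seed Optional integer recorded in the sidecar.
#' @return Invisibly, the base path.
#' @export
writeBeatDataset <- function(dataset, base, seed = NULL) {
  stopifnot(is(dataset, "BeatDataset"))
  dir.create(dirname(base), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(dataset@beats)
  names(df) <- paste0("s", seq_len(ncol(dataset@beats)) - 1L)
  df$label <- dataset@labels
  df$source_db <- dataset@sourceDb
  df$source_record <- dataset@sourceRecord
  utils::write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  meta <- list(fs = dataset@fs, beat_length = ncol(dataset@beats),
               class_names = as.list(dataset@classNames),
               preprocessing = dataset@preprocessing, seed = seed)
  jsonlite::write_json(meta, paste0(base, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(base)
}

#' Read a BeatDataset written by [writeBeatDataset()]
#' @param base Base path (without `.csv`).
#' @return A [BeatDataset-class].
#' @export
readBeatDataset <- function(base) {
  base <- sub("\\.csv$", "", base)
  df <- utils::read.csv(paste0(base, ".csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(base, ".meta.json"))
  sampleCols <- grep("^s[0-9]+$", names(df))
  beatDataset(as.matrix(df[, sampleCols, drop = FALSE]),
              labels = df$label, sourceDb = df$source_db,
              sourceRecord = df$source_record,
              classNames = unlist(meta$class_names), fs = meta$fs,
              preprocessing = list(
                applied = meta$preprocessing$applied,
                pending = meta$preprocessing$pending))
}
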