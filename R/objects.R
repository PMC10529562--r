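#' Construct an EcgRecord
#'
#' @param signal Numeric vector (one lead) or matrix (rows = samples,
#'   columns = leads), amplitudes in mV.
#' @param fs Sampling frequency in Hz.
#' @param leadNames Lead labels, one per column.
#' @param recordId Record identifier.
#' @param sourceDb Source database tag.
#' @param provenance Optional named list of processing notes.
#' @return A validated [EcgRecord-class] object.
#' @examples
#' rec <- ecgRecord(sin(2 * pi * 5 * seq(0, 1, by = 1 / 360)), fs = 360)
#' samplingRate(rec)
#' @export
ecgRecord <- function(signal, fs, leadNames = NULL, recordId = "record",
                      sourceDb = "unknown", provenance = list()) {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  storage.mode(signal) <- "double"
  if (is.null(leadNames))
    leadNames <- if (!is.null(colnames(signal))) colnames(signal)
                 else paste0("lead", seq_len(ncol(signal)) - 1L)
  new("EcgRecord", recordId = as.character(recordId), signal = signal,
      fs = as.numeric(fs), leadNames = as.character(leadNames),
      sourceDb = as.character(sourceDb), provenance = provenance)
}

#' Construct a BeatAnnotationSet
#'
#' @param indices 0-based sample indices of the R peaks, strictly increasing.
#' @param symbols Single-character beat codes, one per index.
#' @return A validated [BeatAnnotationSet-class] object.
#' @examples
#' beatAnnotationSet(c(200, 500, 900), c("N", "V", "N"))
#' @export
beatAnnotationSet <- function(indices = integer(0), symbols = character(0)) {
  new("BeatAnnotationSet", indices = as.integer(indices),
      symbols = as.character(symbols))
}

#' Construct a WindowSpec
#'
#' If `M` and `N` are not given they are derived from `L` by [splitWindow()].
#'
#' @param L Samples per beat at the target frequency.
#' @param fsTarget Unified sampling frequency in Hz.
#' @param M,N Optional explicit pre/post R-peak sample counts.
#' @return A validated [WindowSpec-class] object.
#' @examples
#' windowSpec(260, 360)  # M = 129, N = 130
#' @export
windowSpec <- function(L = 260, fsTarget = 360, M = NULL, N = NULL) {
  L <- as.integer(L)
  if (is.null(M) || is.null(N)) {
    mn <- splitWindow(L)
    M <- mn[[1]]; N <- mn[[2]]
  }
  new("WindowSpec", L = L, M = as.integer(M), N = as.integer(N),
      fsTarget = as.numeric(fsTarget))
}

#' Construct a BeatDataset
#'
#' @param beats m x n numeric matrix of beats.
#' @param labels Integer class ids, length m.
#' @param sourceDb,sourceRecord Per-beat provenance (recycled if scalar).
#' @param classNames Optional class names.
#' @param fs Sampling frequency of the beat samples.
#' @param preprocessing List with `applied` and `pending` operator names.
#' @param dropLog data.frame of discarded beats.
#' @return A validated [BeatDataset-class] object.
#' @export
beatDataset <- function(beats, labels, sourceDb = "unknown",
                        sourceRecord = "unknown", classNames = character(0),
                        fs = 360,
                        preprocessing = list(applied = "none",
                                             pending = "none"),
                        dropLog = NULL) {
  beats <- as.matrix(beats)
  storage.mode(beats) <- "double"
  m <- nrow(beats)
  if (length(sourceDb) == 1) sourceDb <- rep(sourceDb, m)
  if (length(sourceRecord) == 1) sourceRecord <- rep(sourceRecord, m)
  if (is.null(dropLog))
    dropLog <- data.frame(record_id = character(0), r_index = integer(0),
                          reason = character(0))
  new("BeatDataset", beats = beats, labels = as.integer(labels),
      sourceDb = as.character(sourceDb),
      sourceRecord = as.character(sourceRecord),
      classNames = as.character(classNames), fs = as.numeric(fs),
      preprocessing = preprocessing, dropLog = dropLog)
}

#' Construct a TrainConfig
#'
#' @param learningRate Adam step size; default 0.001.
#' @param maxEpochs Epoch budget; default 200.
#' @param batchSize Minibatch size; default 300.
#' @param validationFraction Fraction of the training set held out and
#'   monitored each epoch; default 0 (train on everything).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @param optimizer Only "adam" is implemented.
#' @return A validated [TrainConfig-class] object.
#' @export
trainConfig <- function(learningRate = 0.001, maxEpochs = 200,
                        batchSize = 300, validationFraction = 0, seed = 1,
                        optimizer = "adam") {
  optimizer <- match.arg(optimizer)
  new("TrainConfig", optimizer = optimizer,
      learningRate = as.numeric(learningRate),
      maxEpochs = as.integer(maxEpochs), batchSize = as.integer(batchSize),
      validationFraction = as.numeric(validationFraction),
      seed = as.integer(seed))
}

## ---- accessors ----

#' @describeIn samplingRate sampling frequency of a record
#' @export
setMethod("samplingRate", "EcgRecord", function(object) object@fs)

#' @describeIn samplingRate sampling frequency of the beats in a dataset
#' @export
setMethod("samplingRate", "BeatDataset", function(object) object@fs)

#' @describeIn leadNames lead labels of a record
#' @export
setMethod("leadNames", "EcgRecord", function(object) object@leadNames)

#' @describeIn beatMatrix beat matrix of a dataset
#' @export
setMethod("beatMatrix", "BeatDataset", function(object) object@beats)

#' @describeIn beatLabels labels of a dataset
#' @export
setMethod("beatLabels", "BeatDataset", function(object) object@labels)

#' @describeIn nBeats number of beats in a dataset
#' @export
setMethod("nBeats", "BeatDataset", function(object) nrow(object@beats))

#' Number of annotations in a BeatAnnotationSet
#' @param x A [BeatAnnotationSet].
#' @return Integer count.
#' @export
setMethod("length", "BeatAnnotationSet", function(x) length(x@indices))

#' Per-beat provenance of a dataset
#' @param dataset A [BeatDataset].
#' @return data.frame with columns source_db and source_record.
#' @export
beatProvenance <- function(dataset) {
  stopifnot(is(dataset, "BeatDataset"))
  data.frame(source_db = dataset@sourceDb,
             source_record = dataset@sourceRecord)
}

#' Extraction/preprocessing drop log of a dataset
#' @param dataset A [BeatDataset].
#' @return data.frame with columns record_id, r_index, reason.
#' @export
dropLog <- function(dataset) {
  stopifnot(is(dataset, "BeatDataset"))
  dataset@dropLog
}

#' Write the drop log as CSV
#' @param dataset A [BeatDataset].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
writeDropLog <- function(dataset, path) {
  utils::write.csv(dropLog(dataset), path, row.names = FALSE)
  invisible(path)
}

## ---- show methods ----

setMethod("show", "EcgRecord", function(object) {
  cat(sprintf("EcgRecord \"%s\" [%s]: %d samples x %d lead(s) (%s) at %g Hz\n",
              object@recordId, object@sourceDb, nrow(object@signal),
              ncol(object@signal), paste(object@leadNames, collapse = ", "),
              object@fs))
  invisible(NULL)
})

setMethod("show", "BeatAnnotationSet", function(object) {
  cat(sprintf("BeatAnnotationSet: %d annotations", length(object@indices)))
  if (length(object@indices)) {
    tab <- sort(table(object@symbols), decreasing = TRUE)
    cat(" (", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), ")",
        sep = "")
  }
  cat("\n")
  invisible(NULL)
})

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec: L = %d (M = %d before, N = %d after R) at %g Hz\n",
              object@L, object@M, object@N, object@fsTarget))
  invisible(NULL)
})

setMethod("show", "ClassMap", function(object) {
  cat(sprintf("ClassMap \"%s\": %d classes, %d mapped codes, %d excluded\n",
              object@scheme, length(object@classNames), length(object@codes),
              length(object@excludedCodes)))
  invisible(NULL)
})

setMethod("show", "BeatDataset", function(object) {
  cat(sprintf("BeatDataset: %d beats x %d samples at %g Hz\n",
              nrow(object@beats), ncol(object@beats), object@fs))
  cat(sprintf("  preprocessing: applied = %s, pending = %s\n",
              object@preprocessing$applied, object@preprocessing$pending))
  if (nrow(object@beats)) {
    tab <- table(factor(object@labels))
    cat(sprintf("  classes: %s\n",
                paste(sprintf("%s:%d", names(tab), tab), collapse = " ")))
  }
  if (nrow(object@dropLog))
    cat(sprintf("  dropped: %d beats (see dropLog())\n", nrow(object@dropLog)))
  invisible(NULL)
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult (seed %d, test fraction %g): %d train / %d test\n",
              object@seed, object@testFraction, nBeats(object@train),
              nBeats(object@test)))
  invisible(NULL)
})

setMethod("show", "EvalReport", function(object) {
  tot <- sum(object@confusion)
  cat(sprintf("EvalReport: %d beats, accuracy %.2f%%, %d misclassified\n",
              tot, 100 * object@overallAccuracy, object@misclassified))
  cat(sprintf("  macro precision %.2f, macro recall %.2f, macro F1 %.2f\n",
              object@macroPrecision, object@macroRecall, object@macroF1))
  pc <- object@perClass
  pc$precision <- round(pc$precision, 2)
  pc$recall <- round(pc$recall, 2)
  pc$f1 <- round(pc$f1, 2)
  print(pc, row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "FcNetwork", function(object) {
  cat(sprintf(
    "FcNetwork: %d inputs -> %d x %d rectified units (dropout %.2f) -> %d softmax [%s]\n",
    object@inputUnits, object@nHidden, object@hiddenUnits, object@dropout,
    object@nClasses, if (object@trained) "trained" else "untrained"))
  invisible(NULL)
})

setMethod("show", "ResNetwork", function(object) {
  cat(sprintf(
    "ResNetwork: input length %d, blocks (%s) kernels (%s), %d classes [%s]\n",
    object@inputLength, paste(object@channels, collapse = ", "),
    paste(object@kernelSizes, collapse = ", "), object@nClasses,
    if (object@trained) "trained" else "untrained"))
  invisible(NULL)
})

setMethod("show", "DatabaseProfile", function(object) {
  cat(sprintf(
    "DatabaseProfile \"%s\": %g Hz, gain %g, offset %g mV, HR %g-%g bpm, %d classes\n",
    object@name, object@fs, object@gain, object@offset, object@heartRate[1],
    object@heartRate[2], sum(object@classMix > 0)))
  invisible(NULL)
})
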