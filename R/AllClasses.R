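#' @import methods
NULL

#' EcgRecord: a multi-lead sampled ECG signal
#'
#' Container for one ECG record: a samples-by-leads matrix of amplitudes in
#' millivolts, the sampling frequency, ordered lead names and a source-database
#' tag. All leads share one length and all amplitudes must be finite.
#'
#' @slot recordId Record identifier (character scalar).
#' @slot signal Numeric matrix, rows = time samples, columns = leads, in mV.
#' @slot fs Sampling frequency in Hz (positive scalar).
#' @slot leadNames Character vector of lead labels, one per signal column.
#' @slot sourceDb Source database tag (character scalar).
#' @slot provenance Named list of processing notes (e.g. which lead was
#'   selected at read time).
#'
#' @seealso [ecgRecord()], [readEcgRecord()], [writeEcgRecord()]
#' @export
setClass("EcgRecord",
  representation(
    recordId = "character",
    signal = "matrix",
    fs = "numeric",
    leadNames = "character",
    sourceDb = "character",
    provenance = "list"
  ),
  prototype(
    recordId = "record", signal = matrix(numeric(0), 0, 1),
    fs = 360, leadNames = "MLII", sourceDb = "unknown", provenance = list()
  )
)

setValidity("EcgRecord", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive finite number")
  if (!is.numeric(object@signal))
    msg <- c(msg, "signal must be a numeric matrix")
  else if (anyNA(object@signal) || any(!is.finite(object@signal)))
    msg <- c(msg, "signal amplitudes must all be finite")
  if (ncol(object@signal) != length(object@leadNames))
    msg <- c(msg, "one lead name is required per signal column")
  if (length(object@recordId) != 1)
    msg <- c(msg, "recordId must be a single string")
  if (length(msg)) msg else TRUE
})

#' BeatAnnotationSet: R-peak positions and beat codes
#'
#' Strictly increasing 0-based sample indices of annotated R peaks, paired
#' with one single-character annotation code each. Non-beat codes (rhythm
#' changes, artifacts) are retained here and excluded later by the class map.
#'
#' @slot indices Integer vector of 0-based sample offsets, strictly increasing.
#' @slot symbols Character vector of single-character annotation codes.
#'
#' @seealso [beatAnnotationSet()], [readBeatAnnotations()]
#' @export
setClass("BeatAnnotationSet",
  representation(indices = "integer", symbols = "character"),
  prototype(indices = integer(0), symbols = character(0))
)

setValidity("BeatAnnotationSet", function(object) {
  msg <- character(0)
  if (length(object@indices) != length(object@symbols))
    msg <- c(msg, "indices and symbols must have equal length")
  if (length(object@indices)) {
    if (any(object@indices < 0))
      msg <- c(msg, "annotation indices must be non-negative")
    if (length(object@indices) > 1 && any(diff(object@indices) <= 0))
      msg <- c(msg, "annotation indices must be strictly increasing")
  }
  if (any(nchar(object@symbols) != 1))
    msg <- c(msg, "annotation symbols must be single characters")
  if (length(msg)) msg else TRUE
})

#' WindowSpec: the per-beat sampling window
#'
#' Holds the number of samples per extracted heartbeat `L`, its split into
#' `M` samples before and `N` samples after the R peak (M + N + 1 == L), and
#' the unified target sampling frequency. The admissible range of `L` follows
#' from resting heart-rate physiology: at `fsTarget` Hz a 60-100 bpm beat
#' spans between 0.6*fsTarget and fsTarget samples, so `L` must lie in that
#' interval.
#'
#' @slot L Integer, samples per beat.
#' @slot M Integer, samples taken before the R peak.
#' @slot N Integer, samples taken after the R peak.
#' @slot fsTarget Numeric, unified sampling frequency in Hz.
#'
#' @seealso [windowSpec()], [numOfSample()], [splitWindow()]
#' @export
setClass("WindowSpec",
  representation(L = "integer", M = "integer", N = "integer",
                 fsTarget = "numeric"),
  prototype(L = 260L, M = 129L, N = 130L, fsTarget = 360)
)

setValidity("WindowSpec", function(object) {
  msg <- character(0)
  if (object@M < 0 || object@N < 0)
    msg <- c(msg, "M and N must be non-negative")
  if (object@M + object@N + 1L != object@L)
    msg <- c(msg, "M + N + 1 must equal L")
  if (length(object@fsTarget) != 1 || object@fsTarget <= 0)
    msg <- c(msg, "fsTarget must be a single positive number")
  else if (object@L < 0.6 * object@fsTarget || object@L > object@fsTarget)
    msg <- c(msg, sprintf(
      "L = %d outside the physiological window [0.6*fsTarget, fsTarget] = [%g, %g]",
      object@L, 0.6 * object@fsTarget, object@fsTarget))
  if (length(msg)) msg else TRUE
})

#' ClassMap: beat-code to class-id harmonization table
#'
#' Maps single-character beat annotation codes onto integer class ids with
#' human-readable names and abbreviations. Codes listed as excluded (non-beat
#' marks and superclasses subsuming retained classes) are dropped at
#' extraction time; codes in neither set are skipped and counted.
#'
#' @slot scheme Scheme identifier (character scalar).
#' @slot codes Named integer vector: names are beat codes, values class ids.
#' @slot classNames Character vector of class names, indexed by class id + 1.
#' @slot classAbbrev Character vector of class abbreviations, same indexing.
#' @slot excludedCodes Character vector of codes deliberately excluded.
#'
#' @seealso [buildClassMap()]
#' @export
setClass("ClassMap",
  representation(
    scheme = "character",
    codes = "integer",
    classNames = "character",
    classAbbrev = "character",
    excludedCodes = "character"
  )
)

setValidity("ClassMap", function(object) {
  msg <- character(0)
  if (is.null(names(object@codes)) || anyDuplicated(names(object@codes)))
    msg <- c(msg, "each beat code may be assigned to exactly one class")
  nc <- length(object@classNames)
  if (length(object@classAbbrev) != nc)
    msg <- c(msg, "classNames and classAbbrev must have equal length")
  if (length(object@codes) &&
      (min(object@codes) < 0 || max(object@codes) >= nc))
    msg <- c(msg, "class ids must lie in [0, nClasses - 1]")
  if (any(names(object@codes) %in% object@excludedCodes))
    msg <- c(msg, "mapped and excluded code sets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' BeatDataset: the beat matrix with labels and provenance
#'
#' The central dataset object: an m x n matrix `beats` (m heartbeats, each a
#' row of n amplitude samples), integer class labels and per-beat provenance
#' (source database and record). A drop log records beats discarded during
#' extraction or preprocessing. `preprocessing` records which operator has
#' been applied ("none" if raw) and whether a column-wise operator is still
#' pending (to be fitted on the training split only).
#'
#' @slot beats Numeric matrix, m beats x n samples.
#' @slot labels Integer vector of class ids, length m.
#' @slot sourceDb Character vector, length m.
#' @slot sourceRecord Character vector, length m.
#' @slot classNames Character vector naming the class ids.
#' @slot fs Numeric, sampling frequency of the beat samples in Hz.
#' @slot preprocessing List with elements `applied` (character) and
#'   `pending` (character).
#' @slot dropLog data.frame with columns record_id, r_index, reason.
#'
#' @seealso [beatDataset()], [integrateDatabases()], [stratifiedSplit()]
#' @export
setClass("BeatDataset",
  representation(
    beats = "matrix",
    labels = "integer",
    sourceDb = "character",
    sourceRecord = "character",
    classNames = "character",
    fs = "numeric",
    preprocessing = "list",
    dropLog = "data.frame"
  ),
  prototype(
    beats = matrix(numeric(0), 0, 0), labels = integer(0),
    sourceDb = character(0), sourceRecord = character(0),
    classNames = character(0), fs = 360,
    preprocessing = list(applied = "none", pending = "none"),
    dropLog = data.frame(record_id = character(0), r_index = integer(0),
                         reason = character(0))
  )
)

setValidity("BeatDataset", function(object) {
  msg <- character(0)
  m <- nrow(object@beats)
  if (length(object@labels) != m)
    msg <- c(msg, "labels must have one entry per beat row")
  if (length(object@sourceDb) != m || length(object@sourceRecord) != m)
    msg <- c(msg, "provenance vectors must have one entry per beat row")
  if (m && (anyNA(object@beats) || any(!is.finite(object@beats))))
    msg <- c(msg, "beat samples must all be finite")
  if (length(msg)) msg else TRUE
})

#' SplitResult: a stratified train/test partition
#'
#' @slot train Training [BeatDataset].
#' @slot test Test [BeatDataset].
#' @slot perClassCounts data.frame with columns class_id, class, total,
#'   train, test.
#' @slot seed Integer seed used for the within-class shuffles.
#' @slot testFraction Numeric, requested test proportion.
#'
#' @seealso [stratifiedSplit()]
#' @export
setClass("SplitResult",
  representation(train = "BeatDataset", test = "BeatDataset",
                 perClassCounts = "data.frame", seed = "integer",
                 testFraction = "numeric")
)

#' EvalReport: per-class and overall classification metrics
#'
#' Confusion matrix (rows = true class, columns = predicted), per-class
#' precision/recall/F1/support, overall accuracy, misclassified count and
#' macro-averaged metrics over classes with positive support.
#'
#' @slot confusion Integer matrix of counts, rows = true classes.
#' @slot perClass data.frame: class_id, class, precision, recall, f1, support.
#' @slot overallAccuracy Numeric in [0, 1].
#' @slot misclassified Integer count of wrongly predicted beats.
#' @slot macroPrecision,macroRecall,macroF1 Numeric macro averages.
#'
#' @seealso [evaluateModel()], [evalReportFromConfusion()]
#' @export
setClass("EvalReport",
  representation(
    confusion = "matrix",
    perClass = "data.frame",
    overallAccuracy = "numeric",
    misclassified = "integer",
    macroPrecision = "numeric",
    macroRecall = "numeric",
    macroF1 = "numeric"
  )
)

setValidity("EvalReport", function(object) {
  msg <- character(0)
  if (nrow(object@confusion) != ncol(object@confusion))
    msg <- c(msg, "confusion matrix must be square")
  tot <- sum(object@confusion)
  if (tot > 0) {
    acc <- sum(diag(object@confusion)) / tot
    if (abs(acc - object@overallAccuracy) > 1e-12)
      msg <- c(msg, "overallAccuracy must equal trace/total")
    if (object@misclassified != tot - sum(diag(object@confusion)))
      msg <- c(msg, "misclassified must equal total - trace")
  }
  if (length(msg)) msg else TRUE
})

#' MorphologySpec: five-bump Gaussian beat morphology
#'
#' Parameterizes one heartbeat class as the sum of five Gaussian bumps
#' modeling the P, Q, R, S and T waves, each with an amplitude (mV), a center
#' (seconds relative to the R peak) and a width (seconds, the Gaussian sigma),
#' plus beat-to-beat jitter scales for amplitude and timing. The R bump must
#' carry the largest absolute amplitude so that the annotated R index is the
#' beat's dominant deflection.
#'
#' @slot className Class name this morphology emulates.
#' @slot amplitudes Named numeric length 5 (P, Q, R, S, T), mV.
#' @slot centers Named numeric length 5, seconds relative to the R peak.
#' @slot widths Named numeric length 5, positive seconds.
#' @slot amplitudeJitter Relative sd of per-beat amplitude jitter.
#' @slot timingJitter Sd of per-beat center jitter in seconds (P/T only).
#'
#' @seealso [morphologySpec()], [classMorphologies()]
#' @export
setClass("MorphologySpec",
  representation(
    className = "character",
    amplitudes = "numeric",
    centers = "numeric",
    widths = "numeric",
    amplitudeJitter = "numeric",
    timingJitter = "numeric"
  )
)

setValidity("MorphologySpec", function(object) {
  msg <- character(0)
  for (s in c("amplitudes", "centers", "widths"))
    if (length(slot(object, s)) != 5)
      msg <- c(msg, sprintf("%s must have length 5 (P, Q, R, S, T)", s))
  if (any(object@widths <= 0))
    msg <- c(msg, "widths must be positive")
  if (length(object@amplitudes) == 5 &&
      which.max(abs(object@amplitudes)) != 3L)
    msg <- c(msg, "the R bump (3rd) must have the largest absolute amplitude")
  if (length(msg)) msg else TRUE
})

#' DatabaseProfile: synthetic source-database characteristics
#'
#' Describes one emulated source database: its sampling frequency, an
#' amplitude gain and offset (the scale differences real databases show),
#' the three classical ECG noise processes (baseline wander, powerline
#' interference, electromyographic noise) with their levels in mV, a resting
#' heart-rate range in bpm and a mixture over beat classes.
#'
#' @slot name Database tag.
#' @slot fs Sampling frequency in Hz.
#' @slot gain Multiplicative amplitude factor applied to the clean signal.
#' @slot offset Additive amplitude offset in mV.
#' @slot baselineWander Numeric `c(freqLo, freqHi, amp)`: sinusoidal drift
#'   frequency range (Hz) and amplitude (mV).
#' @slot powerline Numeric `c(freq, amp)`: mains frequency (50 or 60 Hz) and
#'   amplitude (mV).
#' @slot emg Numeric scalar: sd of the band-limited (5 Hz-Nyquist)
#'   electromyographic noise in mV.
#' @slot heartRate Numeric `c(lo, hi)` resting range in bpm.
#' @slot classMix Named numeric vector of mixture proportions (sums to 1);
#'   names are class ids as characters.
#'
#' @seealso [databaseProfile()], [defaultProfiles()], [generateRecord()]
#' @export
setClass("DatabaseProfile",
  representation(
    name = "character",
    fs = "numeric",
    gain = "numeric",
    offset = "numeric",
    baselineWander = "numeric",
    powerline = "numeric",
    emg = "numeric",
    heartRate = "numeric",
    classMix = "numeric"
  )
)

setValidity("DatabaseProfile", function(object) {
  msg <- character(0)
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (abs(sum(object@classMix) - 1) > 1e-8)
    msg <- c(msg, "classMix must sum to 1")
  if (any(object@classMix < 0))
    msg <- c(msg, "classMix proportions must be non-negative")
  if (length(object@heartRate) != 2 || diff(object@heartRate) < 0)
    msg <- c(msg, "heartRate must be c(lo, hi) with lo <= hi")
  if (length(msg)) msg else TRUE
})

#' FcNetwork: the 5-layer fully connected reference classifier
#'
#' Input batch-normalization stage followed by four fully connected hidden
#' layers of 256 rectified units with dropout, and a softmax output layer —
#' five weighted layers in total.
#'
#' @slot inputUnits Integer, input length (samples per beat).
#' @slot hiddenUnits Integer, units per hidden layer.
#' @slot nHidden Integer, number of hidden layers.
#' @slot nClasses Integer, output units.
#' @slot dropout Numeric dropout probability in the hidden layers.
#' @slot params Named list of weight matrices / vectors.
#' @slot history data.frame of per-epoch loss/accuracy (empty if untrained).
#' @slot trained Logical.
#'
#' @seealso [buildFcNetwork()], [trainModel()]
#' @export
setClass("FcNetwork",
  representation(
    inputUnits = "integer", hiddenUnits = "integer", nHidden = "integer",
    nClasses = "integer", dropout = "numeric", params = "list",
    history = "data.frame", trained = "logical"
  )
)

#' ResNetwork: the 12-layer 1-D residual reference classifier
#'
#' Three structurally identical residual blocks with 64, 128 and 128 channels;
#' each block stacks three 1-D convolutions (kernel lengths 8, 5, 3), each
#' followed by batch normalization and a rectifier, with an identity (or
#' 1x1-projection) shortcut. A strided 1x1 convolution after each of the
#' first two blocks halves the temporal resolution. Global average pooling
#' feeds the final fully connected softmax layer. Main-path weighted layers:
#' 9 block convolutions + 2 downsampling convolutions + 1 fully connected = 12.
#'
#' @slot inputLength Integer, samples per beat.
#' @slot channels Integer vector, channels per block.
#' @slot kernelSizes Integer vector, kernel lengths within each block.
#' @slot nClasses Integer, output units.
#' @slot params Named list of parameter arrays.
#' @slot history data.frame of per-epoch loss/accuracy.
#' @slot trained Logical.
#'
#' @seealso [buildResNetwork()], [trainModel()]
#' @export
setClass("ResNetwork",
  representation(
    inputLength = "integer", channels = "integer", kernelSizes = "integer",
    nClasses = "integer", params = "list", history = "data.frame",
    trained = "logical"
  )
)

#' TrainConfig: optimizer and schedule settings
#'
#' @slot optimizer Character, currently "adam".
#' @slot learningRate Positive numeric step size.
#' @slot maxEpochs Integer epoch budget.
#' @slot batchSize Integer minibatch size (clipped to the dataset size).
#' @slot validationFraction Numeric in [0, 1): held-out fraction monitored
#'   during training.
#' @slot seed Integer seed governing initialization, shuffling and dropout.
#'
#' @seealso [trainConfig()], [trainModel()]
#' @export
setClass("TrainConfig",
  representation(
    optimizer = "character", learningRate = "numeric", maxEpochs = "integer",
    batchSize = "integer", validationFraction = "numeric", seed = "integer"
  ),
  prototype(optimizer = "adam", learningRate = 0.001, maxEpochs = 200L,
            batchSize = 300L, validationFraction = 0, seed = 1L)
)

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (object@learningRate < 0)
    msg <- c(msg, "learningRate must be non-negative")
  if (object@maxEpochs < 1) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (object@validationFraction < 0 || object@validationFraction >= 1)
    msg <- c(msg, "validationFraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})
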