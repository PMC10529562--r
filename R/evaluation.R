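# Per-class precision/recall/F1 tables, confusion matrices, overall accuracy
# and misclassified counts; a comparison harness over preprocessing methods;
# and the held-out-database (inter-patient-style) protocol.

#' Confusion matrix from true and predicted labels
#'
#' @param true,predicted Integer class ids (0-based).
#' @param nClasses Number of classes.
#' @return Integer `nClasses` x `nClasses` matrix, rows = true classes.
#' @export
confusionMatrix <- function(true, predicted, nClasses) {
  stopifnot(length(true) == length(predicted))
  lv <- 0:(nClasses - 1L)
  tab <- table(factor(true, levels = lv), factor(predicted, levels = lv))
  m <- matrix(as.integer(tab), nClasses, nClasses,
              dimnames = list(true = lv, predicted = lv))
  m
}

#' Build an EvalReport from a confusion matrix
#'
#' Computes per-class precision (`diag / column sums`), recall
#' (`diag / row sums`), F1 (harmonic mean, 0 when precision and recall are
#' both 0), support (row sums), overall accuracy (`trace / total`),
#' misclassified count, and macro averages over the classes with positive
#' support (zero-support classes are flagged and excluded from macros).
#'
#' @param confusion Square count matrix, rows = true classes.
#' @param classNames Optional class names.
#' @return An [EvalReport-class].
#' @examples
#' # a two-class tally: 77189 of 77501 first-class beats correct
#' conf <- matrix(c(77189, 0, 312, 0), 2, 2)
#' rep <- evalReportFromConfusion(conf)
#' formatPercent(rep@perClass$recall[1], 3)  # "99.597"
#' @export
evalReportFromConfusion <- function(confusion, classNames = NULL) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  nc <- nrow(confusion)
  support <- rowSums(confusion)
  predTot <- colSums(confusion)
  tp <- diag(confusion)
  precision <- ifelse(predTot > 0, tp / predTot, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  if (is.null(classNames) || length(classNames) != nc)
    classNames <- as.character(0:(nc - 1L))
  perClass <- data.frame(class_id = 0:(nc - 1L), class = classNames,
                         precision = precision, recall = recall, f1 = f1,
                         support = as.integer(support))
  rownames(perClass) <- NULL
  pos <- support > 0
  total <- sum(confusion)
  acc <- if (total > 0) sum(tp) / total else 0
  new("EvalReport",
      confusion = confusion, perClass = perClass, overallAccuracy = acc,
      misclassified = as.integer(total - sum(tp)),
      macroPrecision = mean(precision[pos]),
      macroRecall = mean(recall[pos]),
      macroF1 = mean(f1[pos]))
}

#' Predicted class ids from a model
#' @param model A trained classifier.
#' @param newdata Beat matrix or [BeatDataset-class].
#' @return Integer 0-based class ids.
#' @export
predictClass <- function(model, newdata) {
  max.col(predictProba(model, newdata)) - 1L
}

#' @describeIn evaluateModel evaluate an FC network on a dataset
#' @export
setMethod("evaluateModel", "FcNetwork", function(object, dataset,
                                                 nClasses = NULL) {
  evaluateCore(object, dataset, nClasses %||% object@nClasses)
})

#' @describeIn evaluateModel evaluate a ResNet on a dataset
#' @export
setMethod("evaluateModel", "ResNetwork", function(object, dataset,
                                                  nClasses = NULL) {
  evaluateCore(object, dataset, nClasses %||% object@nClasses)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

evaluateCore <- function(model, dataset, nClasses) {
  stopifnot(is(dataset, "BeatDataset"))
  y <- beatLabels(dataset)
  if (length(y) && max(y) >= nClasses)
    stop("dataset labels exceed the model's class scheme", call. = FALSE)
  pred <- predictClass(model, dataset)
  cn <- if (length(dataset@classNames) == nClasses) dataset@classNames
        else NULL
  evalReportFromConfusion(confusionMatrix(y, pred, nClasses), cn)
}

#' Nearest-centroid baseline classifier
#'
#' Assigns each test beat the class of the nearest (Euclidean) training
#' class centroid. A deliberately simple geometric baseline used as a
#' pipeline sanity check: on clean, separable synthetic beats it should be
#' near-perfect after per-beat normalization.
#'
#' @param train A [BeatDataset-class].
#' @param newdata Beat matrix or [BeatDataset-class].
#' @return Integer predicted class ids.
#' @export
nearestCentroid <- function(train, newdata) {
  X <- asBeatMatrix(newdata)
  labs <- sort(unique(beatLabels(train)))
  cent <- t(vapply(labs, function(cl)
    colMeans(beatMatrix(train)[beatLabels(train) == cl, , drop = FALSE]),
    numeric(ncol(X))))
  d2 <- outer(rowSums(X^2), rowSums(cent^2), "+") - 2 * X %*% t(cent)
  labs[max.col(-d2)]
}

#' Compare preprocessing operators on one corpus
#'
#' Re-runs integration, the stratified split, training and evaluation once
#' per operator, holding the synthetic corpus, window, split fraction and
#' every seed identical across methods, so rows differ only in the
#' preprocessing. Reports, per method, the misclassified count, overall
#' accuracy, macro recall, macro precision and macro F1.
#'
#' @param databases Database descriptors as for [integrateDatabases()].
#' @param methods Character vector of operator names (>= 2, deduplicated
#'   with a warning).
#' @param config A [TrainConfig-class].
#' @param window A [WindowSpec-class].
#' @param classMap A [ClassMap-class].
#' @param testFraction,splitSeed Split parameters shared by all methods.
#' @param nClasses Number of classes for the model (default: map size).
#' @param modelBuilder Function(inputUnits, nClasses, seed) returning an
#'   untrained model; default [buildFcNetwork()].
#' @return data.frame with one row per method and an attribute `"reports"`
#'   (named list of [EvalReport-class]).
#' @export
comparePreprocessing <- function(databases, methods, config,
                                 window = windowSpec(260, 360),
                                 classMap = buildClassMap(),
                                 testFraction = 0.2, splitSeed = 1,
                                 nClasses = NULL,
                                 modelBuilder = buildFcNetwork) {
  if (anyDuplicated(methods)) {
    warning("duplicate preprocessing methods removed", call. = FALSE)
    methods <- unique(methods)
  }
  if (length(methods) < 2)
    stop("comparePreprocessing needs at least two methods", call. = FALSE)
  nClasses <- nClasses %||% length(classMap@classNames)
  rows <- list()
  reports <- list()
  for (mth in methods) {
    ds <- integrateDatabases(databases, window, classMap, preprocessor = mth)
    sp <- stratifiedSplit(ds, testFraction, splitSeed)
    model <- modelBuilder(inputUnits = window@L, nClasses = nClasses,
                          seed = config@seed)
    model <- trainModel(model, sp@train, config)
    rep <- evaluateModel(model, sp@test)
    reports[[mth]] <- rep
    rows[[mth]] <- data.frame(
      method = mth, misclassified = rep@misclassified,
      accuracy = rep@overallAccuracy, macro_recall = rep@macroRecall,
      macro_precision = rep@macroPrecision, macro_f1 = rep@macroF1)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Evaluate a trained model on a wholly held-out database
#'
#' The inter-patient-style protocol: every extractable beat of a database
#' never seen in training is processed with the identical window, class map
#' and preprocessing as the training data and scored as one test set.
#'
#' @param model A trained classifier.
#' @param holdout A database descriptor as for [integrateDatabases()] (a
#'   directory path or a records/annotations list).
#' @param window A [WindowSpec-class] — must match training.
#' @param classMap A [ClassMap-class] — must match training.
#' @param preprocessor Operator name — must match training.
#' @return An [EvalReport-class] over the held-out beats.
#' @export
holdoutDatabaseEval <- function(model, holdout, window = windowSpec(260, 360),
                                classMap = buildClassMap(),
                                preprocessor = "self") {
  ds <- integrateDatabases(list(holdout), window, classMap,
                           preprocessor = preprocessor, pooledStats = TRUE)
  evaluateModel(model, ds)
}

#' Write an EvalReport to disk
#'
#' Produces `report.json` (full precision), `confusion.csv` and
#' `per_class.csv` under the given directory.
#'
#' @param report An [EvalReport-class].
#' @param dir Output directory (created).
#' @return Invisibly, the directory.
#' @export
writeEvalReport <- function(report, dir) {
  stopifnot(is(report, "EvalReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(overall_accuracy = report@overallAccuracy,
         misclassified = report@misclassified,
         macro_precision = report@macroPrecision,
         macro_recall = report@macroRecall,
         macro_f1 = report@macroF1,
         per_class = report@perClass),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(report@confusion),
                   file.path(dir, "confusion.csv"), row.names = TRUE)
  utils::write.csv(report@perClass, file.path(dir, "per_class.csv"),
                   row.names = FALSE)
  invisible(dir)
}
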