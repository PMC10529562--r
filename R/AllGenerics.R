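#' Sampling frequency accessor
#' @param object An [EcgRecord] or [BeatDataset].
#' @return Sampling frequency in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' Lead name accessor
#' @param object An [EcgRecord].
#' @return Character vector of lead labels.
#' @export
setGeneric("leadNames", function(object) standardGeneric("leadNames"))

#' Beat matrix accessor
#' @param object A [BeatDataset].
#' @return The m x n numeric matrix of beats.
#' @export
setGeneric("beatMatrix", function(object) standardGeneric("beatMatrix"))

#' Beat label accessor
#' @param object A [BeatDataset].
#' @return Integer vector of class ids.
#' @export
setGeneric("beatLabels", function(object) standardGeneric("beatLabels"))

#' Number of beats
#' @param object A [BeatDataset].
#' @return Integer beat count.
#' @export
setGeneric("nBeats", function(object) standardGeneric("nBeats"))

#' Number of weighted layers of a model
#'
#' Counts the layers that carry trainable weights on the main path, following
#' the usual deep-architecture naming convention (projection shortcuts are not
#' counted).
#' @param object A model object.
#' @return Integer layer count.
#' @export
setGeneric("layerCount", function(object) standardGeneric("layerCount"))

#' Predict class probabilities
#'
#' Runs a forward pass in inference mode (dropout disabled, batch
#' normalization using running statistics). Deterministic for a given model.
#'
#' @param object A trained [FcNetwork] or [ResNetwork].
#' @param newdata Numeric matrix of beats (rows) or a [BeatDataset].
#' @return Numeric matrix, one row per beat, one column per class; rows are
#'   probability vectors summing to 1.
#' @export
setGeneric("predictProba", function(object, newdata)
  standardGeneric("predictProba"))

#' Train a classifier
#'
#' Minibatch training with the Adam optimizer and the cross-entropy loss.
#' Fully seeded: initialization, shuffling and dropout masks all derive from
#' `config@seed`, so identical calls give identical histories.
#'
#' @param object An untrained (or previously trained) model.
#' @param dataset A [BeatDataset] with labels in `0:(nClasses-1)`.
#' @param config A [TrainConfig].
#' @return The trained model; the per-epoch history is in `history(model)`.
#' @export
setGeneric("trainModel", function(object, dataset, config)
  standardGeneric("trainModel"))

#' Training history accessor
#' @param object A model.
#' @return data.frame with columns epoch, loss, accuracy (and val_loss,
#'   val_accuracy when a validation fraction was used).
#' @export
setGeneric("history", function(object) standardGeneric("history"))

#' Evaluate a classifier on a test set
#'
#' @param object A trained model.
#' @param dataset A [BeatDataset].
#' @param nClasses Number of classes for the confusion table (defaults to the
#'   model's output size).
#' @return An [EvalReport].
#' @export
setGeneric("evaluateModel", function(object, dataset, nClasses = NULL)
  standardGeneric("evaluateModel"))
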